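#' Monthly dry-weight yield from hourly weather
#'
#' Simulates 27 days of growth (27 * 24 hourly steps, `dt = 1/24` day) from a
#' constant 0.5 g/plant seedling, starting at the first hour of the first day
#' of the month and ending on the 23rd hour of the 27th day, and returns the
#' final dry weight. The 27 days are counted from seedling emergence; with a
#' 15-day germination period this corresponds to day 42 post seeding, but the
#' germination offset is bookkeeping only and never simulated.
#'
#' Gaps in the hourly record up to `max_gap_h` hours are filled by linear
#' interpolation; longer gaps invalidate the month.
#'
#' @param weather a weather data frame as returned by [synth_weather()] or
#'   [read_weather_csv()]: columns `time` (POSIXct, UTC) and `temp_K`.
#' @param year,month calendar year and month (1--12) to simulate.
#' @param params a [growth_params()] object.
#' @param w0 initial dry weight (g/plant); default 0.5.
#' @param max_gap_h largest gap (hours) filled by interpolation; default 3.
#' @return Final dry weight (g/plant).
#' @export
monthly_dry_weight <- function(weather, year, month,
                               params = default_growth_params(), w0 = 0.5,
                               max_gap_h = 3) {
  temps <- month_hourly_temps(weather, year, month, max_gap_h)
  traj <- simulate_trajectory(temps, w0 = w0, params = params, dt = 1 / 24)
  traj[length(traj)]
}

## extract the 648 hourly temperatures of the 27-day window of a month,
## interpolating gaps up to max_gap_h hours
month_hourly_temps <- function(weather, year, month, max_gap_h = 3) {
  stopifnot(is.data.frame(weather), all(c("time", "temp_K") %in% names(weather)))
  start <- as.POSIXct(sprintf("%04d-%02d-01 00:00:00", year, month), tz = "UTC")
  hours <- start + 3600 * (0:(27 * 24 - 1))
  idx <- match(as.numeric(hours), as.numeric(weather$time))
  temps <- weather$temp_K[idx]
  if (anyNA(temps)) {
    present <- which(!is.na(temps))
    if (length(present) < 2L || min(present) > 1L || max(present) < length(temps))
      stop(sprintf("month %04d-%02d: window not covered by the weather record",
                   year, month), call. = FALSE)
    gaps <- rle(is.na(temps))
    if (any(gaps$lengths[gaps$values] > max_gap_h))
      stop(sprintf("month %04d-%02d: gap longer than %d h in hourly record",
                   year, month, max_gap_h), call. = FALSE)
    temps <- stats::approx(present, temps[present], xout = seq_along(temps))$y
  }
  temps
}

#' Build the monthly yield table for a span of years
#'
#' One predicted day-27 dry weight per year-month; months whose 27-day window
#' is not fully covered by the weather record (after gap interpolation) are
#' skipped with a warning.
#'
#' @inheritParams monthly_dry_weight
#' @param years integer vector of calendar years to include.
#' @return A data frame of class `yield_table` with columns `year`, `month`,
#'   `yield_g` (g/plant at day 27 post emergence).
#' @examples
#' w <- synth_weather(years = 1, seed = 1)
#' yt <- build_yield_table(w, years = 2017)
#' nrow(yt) # 12
#' @export
build_yield_table <- function(weather, years, params = default_growth_params(),
                              w0 = 0.5, max_gap_h = 3) {
  rows <- list()
  for (y in years) for (m in 1:12) {
    yield <- tryCatch(
      monthly_dry_weight(weather, y, m, params, w0, max_gap_h),
      error = function(e) {
        warning(sprintf("skipping %04d-%02d: %s", y, m, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
    if (!is.null(yield))
      rows[[length(rows) + 1L]] <- data.frame(year = y, month = m,
                                              yield_g = yield)
  }
  if (length(rows) == 0L) stop("no usable months in the weather record",
                               call. = FALSE)
  out <- do.call(rbind, rows)
  class(out) <- c("yield_table", "data.frame")
  out
}

#' Normalize yields by their maximum
#'
#' @param table a `yield_table` (or any data frame with a `yield_g` column),
#'   or a bare numeric vector of yields.
#' @return Numeric vector in (0, 1] with maximum exactly 1, order preserved.
#' @export
normalize_by_max <- function(table) {
  y <- if (is.data.frame(table)) table$yield_g else table
  if (length(y) == 0L) stop("empty yield table", call. = FALSE)
  if (any(!is.finite(y)) || max(y) <= 0)
    stop("yields must be finite with positive maximum", call. = FALSE)
  y / max(y)
}
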