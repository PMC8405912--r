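#' Climate profile for the synthetic hourly weather generator
#'
#' Sinusoidal seasonal and diurnal cycles plus AR(1) noise — the simplest
#' process carrying the features the yield model is sensitive to. Defaults
#' emulate a subtropical south-Florida station (annual mean ~24 degC,
#' mild seasonality, afternoon diurnal peak); this is not a climatological
#' claim.
#'
#' @param mean_K annual mean temperature (K).
#' @param seasonal_amp_K seasonal half-amplitude (K), >= 0.
#' @param diurnal_amp_K diurnal half-amplitude (K), >= 0.
#' @param ar_coef hourly AR(1) coefficient of the noise, `|ar_coef| < 1`.
#' @param ar_sd innovation standard deviation (K), >= 0.
#' @param season_peak_day day of year of the seasonal maximum.
#' @param diurnal_peak_hour hour of day of the diurnal maximum.
#' @return An object of class `climate_profile`.
#' @export
climate_profile <- function(mean_K = 297.15, seasonal_amp_K = 5,
                            diurnal_amp_K = 4, ar_coef = 0.95, ar_sd = 0.6,
                            season_peak_day = 200, diurnal_peak_hour = 15) {
  if (seasonal_amp_K < 0 || diurnal_amp_K < 0 || ar_sd < 0)
    stop("amplitudes and noise sd must be non-negative", call. = FALSE)
  if (abs(ar_coef) >= 1) stop("|ar_coef| must be below 1", call. = FALSE)
  structure(as.list(environment()), class = "climate_profile")
}

#' Generate synthetic hourly weather
#'
#' `8760 * years` hourly records (365-day years; leap days are not
#' generated). Deterministic for a fixed seed.
#'
#' @param profile a [climate_profile()].
#' @param years number of years, >= 1.
#' @param seed integer seed.
#' @param start_year calendar year of the first record; default 2017.
#' @return Data frame with columns `time` (POSIXct, UTC, hourly) and
#'   `temp_K`, plus attribute `source = "synthetic"`.
#' @examples
#' w <- synth_weather(years = 1, seed = 42)
#' range(w$temp_K)
#' @export
synth_weather <- function(profile = climate_profile(), years = 3, seed = 1,
                          start_year = 2017) {
  stopifnot(inherits(profile, "climate_profile"), years >= 1)
  set.seed(as.integer(seed))
  n <- 8760L * as.integer(years)
  hour_idx <- 0:(n - 1L)
  doy <- (hour_idx / 24) %% 365
  hod <- hour_idx %% 24
  seasonal <- profile$seasonal_amp_K *
    cos(2 * pi * (doy - profile$season_peak_day) / 365)
  diurnal <- profile$diurnal_amp_K *
    cos(2 * pi * (hod - profile$diurnal_peak_hour) / 24)
  noise <- if (profile$ar_sd > 0)
    as.numeric(stats::arima.sim(list(ar = profile$ar_coef), n,
                                sd = profile$ar_sd))
  else numeric(n)
  temp <- profile$mean_K + seasonal + diurnal + noise
  ## timestamps skip Feb 29: 365 calendar days per year, 24 hours each
  times <- do.call(c, lapply(seq_len(years), function(y) {
    yr <- start_year + y - 1
    dates <- seq(as.Date(sprintf("%04d-01-01", yr)), by = "day",
                 length.out = 366)
    dates <- dates[format(dates, "%m-%d") != "02-29"][1:365]
    day_start <- as.numeric(as.POSIXct(paste(dates, "00:00:00"), tz = "UTC"))
    as.POSIXct(rep(day_start, each = 24) + rep(3600 * (0:23), times = 365),
               origin = "1970-01-01", tz = "UTC")
  }))
  out <- data.frame(time = times, temp_K = temp)
  attr(out, "source") <- "synthetic"
  attr(out, "profile") <- profile
  out
}

#' Synthetic growth-chamber experiment design
#'
#' Ten day/night temperature regimes (9 h high / 15 h low) spanning the
#' response curve on both sides of the optimum, observation days, and the
#' true parameter set and observation noise used to generate dry weights.
#'
#' @param regimes_C two-column matrix or data frame of (high, low)
#'   temperatures in degC; default 10 regimes from 18/14 to 38/32.
#' @param days observation days post-transplant; default `seq(4, 28, by = 4)`.
#' @param noise_sd Gaussian observation noise sd (g/plant), >= 0; default 0.5.
#' @param true_params the generating [growth_params()].
#' @param w0 dry weight at day 0 (g/plant).
#' @param seed integer seed.
#' @return An object of class `chamber_design`.
#' @export
chamber_design <- function(regimes_C = NULL, days = seq(4, 28, by = 4),
                           noise_sd = 0.5,
                           true_params = default_growth_params(),
                           w0 = 0.5, seed = 1) {
  if (is.null(regimes_C))
    regimes_C <- cbind(high = c(18, 22, 24, 26, 28, 30, 32, 34, 36, 38),
                       low  = c(14, 16, 18, 20, 22, 24, 26, 28, 30, 32))
  regimes_C <- as.matrix(regimes_C)
  if (nrow(regimes_C) < 1L) stop("need at least one regime", call. = FALSE)
  if (noise_sd < 0) stop("noise sd must be non-negative", call. = FALSE)
  structure(list(regimes_C = regimes_C, days = days, noise_sd = noise_sd,
                 true_params = true_params, w0 = w0,
                 seed = as.integer(seed)),
            class = "chamber_design")
}

#' Generate synthetic growth-chamber datasets
#'
#' Dry-weight trajectories from the forward model at each regime's weighted
#' day temperature, with additive Gaussian observation noise (noise-free
#' when `noise_sd = 0`). Noisy observations are floored at 1% of the true
#' value to respect the positive-weight invariant.
#'
#' @param design a [chamber_design()].
#' @return List of [chamber_dataset()] objects, one per regime.
#' @examples
#' sets <- synth_chamber_data(chamber_design(noise_sd = 0))
#' length(sets)
#' @export
synth_chamber_data <- function(design = chamber_design()) {
  stopifnot(inherits(design, "chamber_design"))
  set.seed(design$seed)
  lapply(seq_len(nrow(design$regimes_C)), function(i) {
    high_K <- design$regimes_C[i, 1] + 273.15
    low_K <- design$regimes_C[i, 2] + 273.15
    tw <- weighted_day_temperature(high_K, low_K)
    r <- growth_rate(tw, design$true_params)
    w_true <- design$w0 * (1 + r)^design$days
    w_obs <- w_true + stats::rnorm(length(design$days), 0, design$noise_sd)
    w_obs <- pmax(w_obs, 0.01 * w_true)
    chamber_dataset(regime = i, high_K = high_K, low_K = low_K,
                    day = design$days, dry_weight_g = w_obs,
                    w0 = design$w0)
  })
}

#' End-to-end yield pipeline fixture
#'
#' Three synthetic years of hourly weather, the 36-row monthly yield table,
#' and the fitted scaled-beta yield-input distribution (maximum anchored at
#' 1), mirroring the weather-to-assumption pipeline.
#'
#' @param seed integer seed.
#' @param params a [growth_params()] used for the yield predictions.
#' @return List with `weather`, `yields` (a `yield_table`), `normalized`,
#'   and `beta_fit` (a `scaled_beta`).
#' @export
yield_pipeline_fixture <- function(seed = 1,
                                   params = default_growth_params()) {
  weather <- synth_weather(years = 3, seed = seed)
  yields <- build_yield_table(weather, years = 2017:2019, params = params)
  normalized <- normalize_by_max(yields)
  list(weather = weather, yields = yields, normalized = normalized,
       beta_fit = fit_scaled_beta(normalized))
}
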