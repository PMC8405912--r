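#' Read an hourly weather CSV
#'
#' Expects the FAWN-export-like dialect: a header row and columns
#' `timestamp` (ISO-8601, interpreted as UTC) and `temp_C` (degC, converted
#' to kelvin internally).
#'
#' @param file path to the CSV.
#' @return Data frame with columns `time` (POSIXct, UTC) and `temp_K`.
#' @export
read_weather_csv <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("timestamp", "temp_C") %in% names(df)))
    stop("weather CSV needs columns 'timestamp' and 'temp_C'", call. = FALSE)
  time <- as.POSIXct(df$timestamp, tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                    "%Y-%m-%d %H:%M"))
  if (anyNA(time)) stop("unparseable timestamps in weather CSV", call. = FALSE)
  if (any(diff(as.numeric(time)) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  data.frame(time = time, temp_K = df$temp_C + 273.15)
}

#' Write weather to CSV
#'
#' @param weather a weather data frame (`time`, `temp_K`).
#' @param file output path.
#' @export
write_weather_csv <- function(weather, file) {
  utils::write.csv(
    data.frame(timestamp = format(weather$time, "%Y-%m-%dT%H:%M:%S"),
               temp_C = weather$temp_K - 273.15),
    file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read growth-chamber observations from CSV
#'
#' Columns: `regime`, `T_high_C`, `T_low_C`, `day`, `dry_weight_g`;
#' temperatures in degC (converted to kelvin). Optional column `w0`
#' (default 0.5 g/plant).
#'
#' @param file path to the CSV.
#' @return List of [chamber_dataset()] objects, one per regime.
#' @export
read_chamber_csv <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("regime", "T_high_C", "T_low_C", "day", "dry_weight_g")
  if (!all(need %in% names(df)))
    stop("chamber CSV needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  lapply(split(df, df$regime), function(d) {
    d <- d[order(d$day), ]
    chamber_dataset(regime = d$regime[1],
                    high_K = d$T_high_C[1] + 273.15,
                    low_K = d$T_low_C[1] + 273.15,
                    day = d$day, dry_weight_g = d$dry_weight_g,
                    w0 = if ("w0" %in% names(d)) d$w0[1] else 0.5)
  })
}

#' Write chamber datasets to CSV
#'
#' @param datasets list of [chamber_dataset()] objects.
#' @param file output path.
#' @export
write_chamber_csv <- function(datasets, file) {
  rows <- do.call(rbind, lapply(datasets, function(d)
    data.frame(regime = d$regime, T_high_C = d$high_K - 273.15,
               T_low_C = d$low_K - 273.15, day = d$day,
               dry_weight_g = d$dry_weight_g, w0 = d$w0)))
  utils::write.csv(rows, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read / write an assumption registry as JSON
#'
#' One object per parameter: `{name, family, params, units, truncation}`.
#'
#' @param file path to the JSON file.
#' @return `read_registry` returns an `assumption_registry`.
#' @export
read_registry <- function(file) {
  raw <- jsonlite::fromJSON(file, simplifyVector = FALSE)
  specs <- lapply(raw, function(x)
    assumption(x$name, x$family, x$params, x$units %||% "",
               if (is.null(x$truncation)) NULL
               else as.numeric(unlist(x$truncation))))
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  structure(specs, class = c("assumption_registry", "list"))
}

#' @rdname read_registry
#' @param registry an `assumption_registry`.
#' @export
write_registry <- function(registry, file) {
  out <- lapply(unclass(registry), function(s) {
    x <- list(name = s$name, family = s$family, params = s$params,
              units = s$units)
    if (!is.null(s$truncation)) x$truncation <- s$truncation
    x
  })
  jsonlite::write_json(unname(out), file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
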