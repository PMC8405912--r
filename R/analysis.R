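#' Compare a forecast between two scenarios
#'
#' Welch two-sample t-test for the means and two-sample Kolmogorov--Smirnov
#' test for the distributions.
#'
#' @param a,b forecast samples (numeric, each `n >= 2`); `NA`s dropped.
#' @param forecast optional forecast name carried into the result.
#' @return A one-row data frame of class `comparison_result`: `forecast`,
#'   `t_stat`, `t_p`, `ks_d`, `ks_p`, `n_a`, `n_b`. When both samples have
#'   zero variance the t-test is undefined and reported as `NA` with
#'   `t_defined = FALSE`.
#' @export
compare_scenarios <- function(a, b, forecast = "") {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least two values", call. = FALSE)
  degenerate <- stats::sd(a) == 0 && stats::sd(b) == 0
  if (degenerate) {
    tt <- list(statistic = NA_real_, p.value = NA_real_)
  } else {
    tt <- stats::t.test(a, b, var.equal = FALSE)
  }
  ks <- suppressWarnings(stats::ks.test(a, b))
  structure(data.frame(forecast = forecast,
                       t_stat = unname(tt$statistic), t_p = tt$p.value,
                       t_defined = !degenerate,
                       ks_d = unname(ks$statistic), ks_p = ks$p.value,
                       n_a = length(a), n_b = length(b)),
            class = c("comparison_result", "data.frame"))
}

#' Normal quantile-quantile points
#'
#' Sorted sample values against standard-normal quantiles at plotting
#' positions `(i - 0.5) / n`, for normality assessment of a forecast.
#'
#' @param sample numeric, `n >= 3`; `NA`s dropped.
#' @return Data frame with columns `theoretical` and `sample`, both
#'   monotone non-decreasing.
#' @export
qq_points <- function(sample) {
  sample <- sample[!is.na(sample)]
  n <- length(sample)
  if (n < 3L) stop("need at least three values", call. = FALSE)
  data.frame(theoretical = stats::qnorm(((1:n) - 0.5) / n),
             sample = sort(sample))
}

## evaluate `model` with one parameter moved to a quantile, others at base
sweep_one <- function(model, base, registry, name, p) {
  x <- base
  x[[name]] <- asm_quantile(registry[[name]], p)
  model(x)
}

#' Registry base point
#'
#' The deterministic base input vector: every assumption at its analytic
#' mean.
#'
#' @param registry an `assumption_registry`.
#' @return One-row data frame, one column per parameter.
#' @export
registry_base <- function(registry) {
  as.data.frame(lapply(registry, asm_mean))
}

#' Tornado (univariate low/high) sensitivity
#'
#' For each input parameter, evaluates the forecast with that parameter set
#' to its low and high distribution quantiles while all others stay at base,
#' and ranks parameters by the absolute swing `|high - low|`.
#'
#' @param model function mapping a one-row input data frame to a scalar
#'   forecast value; see [tea_forecast_fn()].
#' @param base one-row data frame of base input values (e.g.
#'   [registry_base()]).
#' @param registry an `assumption_registry`.
#' @param percentiles `c(lo, hi)` sweep quantiles in (0, 1); default
#'   `c(0.1, 0.9)`.
#' @return Data frame of class `tornado_result`, sorted by descending swing:
#'   `parameter`, `low`, `high` (forecast values), `swing`, `ok` (FALSE when
#'   the model failed at an extreme, values `NA`).
#' @export
tornado <- function(model, base, registry, percentiles = c(0.1, 0.9)) {
  if (any(percentiles <= 0 | percentiles >= 1) ||
      percentiles[1] >= percentiles[2])
    stop("percentiles must satisfy 0 < lo < hi < 1", call. = FALSE)
  rows <- lapply(names(registry), function(nm) {
    vals <- vapply(percentiles, function(p) {
      tryCatch(sweep_one(model, base, registry, nm, p),
               error = function(e) NA_real_)
    }, numeric(1))
    data.frame(parameter = nm, low = vals[1], high = vals[2],
               swing = abs(vals[2] - vals[1]), ok = !anyNA(vals))
  })
  out <- do.call(rbind, rows)
  out$swing[!out$ok] <- NA_real_
  out <- out[order(-ifelse(is.na(out$swing), -Inf, out$swing)), ]
  rownames(out) <- NULL
  class(out) <- c("tornado_result", "data.frame")
  out
}

#' @export
plot.tornado_result <- function(x, base_value = NULL, ...) {
  ok <- x[x$ok, ]
  ok <- ok[rev(seq_len(nrow(ok))), ]
  mid <- if (is.null(base_value)) rowMeans(ok[, c("low", "high")]) else
    rep(base_value, nrow(ok))
  graphics::barplot(rbind(ok$low - mid, ok$high - mid), beside = FALSE,
                    horiz = TRUE, names.arg = ok$parameter, las = 1,
                    offset = mid, main = "Tornado sensitivity",
                    xlab = "forecast value", ...)
  invisible(x)
}

#' Spider (percentile-sweep) sensitivity
#'
#' Forecast value for each parameter over a grid of distribution
#' percentiles, the other parameters held at base. All curves intersect at
#' the base point.
#'
#' @inheritParams tornado
#' @param grid percentile grid in (0, 1); default `seq(0.05, 0.95, 0.05)`.
#' @return Data frame of class `spider_result`: `parameter`, `percentile`,
#'   `value`, `ok`.
#' @export
spider <- function(model, base, registry, grid = seq(0.05, 0.95, by = 0.05)) {
  if (any(grid <= 0 | grid >= 1)) stop("grid must lie within (0, 1)",
                                       call. = FALSE)
  rows <- lapply(names(registry), function(nm) {
    vals <- vapply(grid, function(p) {
      tryCatch(sweep_one(model, base, registry, nm, p),
               error = function(e) NA_real_)
    }, numeric(1))
    data.frame(parameter = nm, percentile = grid, value = vals,
               ok = !is.na(vals))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("spider_result", "data.frame")
  out
}

#' @export
plot.spider_result <- function(x, ...) {
  pars <- unique(x$parameter)
  graphics::matplot(
    matrix(x$percentile, ncol = length(pars)) * 100,
    matrix(x$value, ncol = length(pars)),
    type = "l", lty = 1, col = seq_along(pars),
    xlab = "input percentile (%)", ylab = "forecast value",
    main = "Spider sensitivity", ...)
  graphics::legend("topleft", legend = pars, col = seq_along(pars),
                   lty = 1, cex = 0.7, bty = "n")
  invisible(x)
}

#' Contribution to variance by rank correlation
#'
#' Signed share of each input parameter in the variance of a forecast,
#' computed from Spearman rank correlations:
#' `share_i = sign(rho_i) * rho_i^2 / sum_j rho_j^2 * 100`. Absolute shares
#' sum to 100.
#'
#' @param inputs data frame or matrix of sampled input columns
#'   (`n >= 30` rows).
#' @param forecast forecast values, one per row; `NA` rows dropped pairwise.
#' @return Data frame of class `ctv_result`, sorted by descending absolute
#'   share: `parameter`, `rho` (Spearman), `share_pct` (signed).
#' @export
contribution_to_variance <- function(inputs, forecast) {
  inputs <- as.data.frame(inputs)
  keep <- !is.na(forecast)
  inputs <- inputs[keep, , drop = FALSE]
  forecast <- forecast[keep]
  if (nrow(inputs) < 30L) stop("need at least 30 trials", call. = FALSE)
  rho <- vapply(inputs, function(col)
    stats::cor(col, forecast, method = "spearman"), numeric(1))
  denom <- sum(rho^2)
  if (!is.finite(denom) || denom == 0)
    stop("contribution to variance undefined: all rank correlations zero",
         call. = FALSE)
  share <- sign(rho) * rho^2 / denom * 100
  out <- data.frame(parameter = names(rho), rho = unname(rho),
                    share_pct = unname(share))
  out <- out[order(-abs(out$share_pct)), ]
  rownames(out) <- NULL
  class(out) <- c("ctv_result", "data.frame")
  out
}

#' @export
plot.ctv_result <- function(x, ...) {
  y <- rev(x$share_pct)
  graphics::barplot(y, names.arg = rev(x$parameter), horiz = TRUE, las = 1,
                    xlab = "contribution to variance (%)",
                    main = "Contribution to variance", ...)
  invisible(x)
}

#' Extremal trials of a forecast
#'
#' The full input rows of the trials attaining the minimum and maximum of a
#' forecast, and the trial whose forecast lies nearest the sample mean. Ties
#' are broken by the lowest trial index.
#'
#' @param records a `tea_trials` data frame (or any data frame with the
#'   forecast column).
#' @param forecast name of the forecast column.
#' @return A list of one-row data frames `minimum`, `nearest_mean`,
#'   `maximum`.
#' @export
extremal_trials <- function(records, forecast) {
  v <- records[[forecast]]
  if (is.null(v)) stop("unknown forecast column: ", forecast, call. = FALSE)
  ok <- which(!is.na(v))
  if (length(ok) == 0L) stop("no valid forecast values", call. = FALSE)
  v_ok <- v[ok]
  i_min <- ok[which.min(v_ok)]
  i_max <- ok[which.max(v_ok)]
  i_mean <- ok[which.min(abs(v_ok - mean(v_ok)))]
  list(minimum = records[i_min, , drop = FALSE],
       nearest_mean = records[i_mean, , drop = FALSE],
       maximum = records[i_max, , drop = FALSE])
}

#' Forecast evaluator for sensitivity sweeps
#'
#' Wraps the surrogate model as a function of a one-row input data frame,
#' for use with [tornado()] and [spider()].
#'
#' @param equipment an [equipment_spec()].
#' @param econ an [econ_config()].
#' @param price selling price ($/g).
#' @param forecast one of `"irr_after_tax"`, `"cogs_usd_g"`,
#'   `"annual_throughput_kg"`, `"purity"`.
#' @return `function(inputs)` returning the scalar forecast.
#' @export
tea_forecast_fn <- function(equipment = equipment_spec(),
                            econ = econ_config(), price = 20,
                            forecast = c("irr_after_tax", "cogs_usd_g",
                                         "annual_throughput_kg", "purity")) {
  forecast <- match.arg(forecast)
  function(inputs) {
    e <- run_tea(as.data.frame(inputs), equipment, econ, price)
    e[[forecast]]
  }
}
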