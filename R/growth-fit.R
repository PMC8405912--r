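#' Growth-chamber dataset
#'
#' One chamber regime: constant high/low temperatures held for fixed hour
#' splits each day, with dry-weight observations at days post-transplant.
#' Daily model steps for a regime use [weighted_day_temperature()].
#'
#' @param regime regime identifier (character or numeric).
#' @param high_K,low_K high and low temperatures (K).
#' @param day observation days post-transplant, strictly increasing, > 0.
#' @param dry_weight_g observed dry weights (g/plant), > 0.
#' @param h_high,h_low hours per day at each temperature (default 9/15).
#' @param w0 dry weight at day 0 (g/plant); default 0.5.
#' @return An object of class `chamber_dataset`.
#' @export
chamber_dataset <- function(regime, high_K, low_K, day, dry_weight_g,
                            h_high = 9, h_low = 15, w0 = 0.5) {
  if (length(day) != length(dry_weight_g))
    stop("day and dry_weight_g must have equal length", call. = FALSE)
  if (any(diff(day) <= 0)) stop("days must be strictly increasing", call. = FALSE)
  if (any(dry_weight_g <= 0)) stop("dry weights must be positive", call. = FALSE)
  high_K <- unname(high_K); low_K <- unname(low_K)
  structure(list(regime = regime, high_K = high_K, low_K = low_K,
                 h_high = h_high, h_low = h_low, w0 = w0,
                 day = unname(as.numeric(day)),
                 dry_weight_g = unname(as.numeric(dry_weight_g)),
                 temp_K = weighted_day_temperature(high_K, low_K, h_high, h_low)),
            class = "chamber_dataset")
}

#' @export
print.chamber_dataset <- function(x, ...) {
  cat(sprintf("Chamber regime %s: %.2f/%.2f K (%g/%g h), %d observations\n",
              format(x$regime), x$high_K, x$low_K, x$h_high, x$h_low,
              length(x$day)))
  invisible(x)
}

## model prediction for one regime: daily relative rate at the weighted day
## temperature, compounded over (possibly fractional) days
predict_chamber <- function(dataset, params) {
  r <- growth_rate(dataset$temp_K, params)
  dataset$w0 * (1 + r)^dataset$day
}

pooled_obs <- function(datasets) {
  list(pred = function(params) unlist(lapply(datasets, predict_chamber, params)),
       obs = unlist(lapply(datasets, `[[`, "dry_weight_g")))
}

#' Fit the temperature-response growth model to chamber data
#'
#' Finds the parameter set minimising the pooled root mean squared error
#' between model predictions and dry-weight observations across all supplied
#' chamber regimes, weighting every observation equally. Optimisation is a
#' deterministic two-stage local search (Nelder--Mead followed by BFGS,
#' restarted until the RMSE improves by less than `tol`) on the transformed
#' scale `(log A, log k, S, log H)`, which enforces the positivity bounds.
#'
#' @param datasets a single [chamber_dataset()] or a list of them, each with
#'   at least two observations.
#' @param init initial [growth_params()] guess.
#' @param tol convergence tolerance on the RMSE (g/plant); default 1e-8.
#' @param max_restarts maximum optimiser restarts.
#' @return An object of class `growth_fit` with elements `params`
#'   (`growth_params`), `rmse` (g/plant, pooled), `r2`, `n_obs`, `converged`,
#'   `init`, and the data. The returned RMSE never exceeds the RMSE of
#'   `init`.
#' @examples
#' sets <- synth_chamber_data(chamber_design(noise_sd = 0))
#' fit <- fit_growth(sets, init = default_growth_params())
#' coef(fit)
#' @export
fit_growth <- function(datasets, init = default_growth_params(),
                       tol = 1e-8, max_restarts = 6L) {
  if (inherits(datasets, "chamber_dataset")) datasets <- list(datasets)
  if (length(datasets) < 1L ||
      !all(vapply(datasets, inherits, logical(1), "chamber_dataset")))
    stop("datasets must be chamber_dataset objects", call. = FALSE)
  if (any(vapply(datasets, function(d) length(d$day), integer(1)) < 2L))
    stop("each dataset needs at least two observations", call. = FALSE)
  stopifnot(inherits(init, "growth_params"))

  po <- pooled_obs(datasets)
  objective <- function(theta) {
    p <- growth_params(exp(theta[1]), exp(theta[2]), theta[3], exp(theta[4]))
    pred <- po$pred(p)
    if (any(!is.finite(pred))) return(1e12)
    rmse(pred, po$obs)
  }
  theta <- c(log(init$A), log(init$k), init$S, log(init$H))
  best <- objective(theta)
  rmse_init <- best
  converged <- FALSE
  for (i in seq_len(max_restarts)) {
    nm <- stats::optim(theta, objective, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-12))
    bf <- tryCatch(
      stats::optim(nm$par, objective, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) nm)
    cand <- if (bf$value < nm$value) bf else nm
    improvement <- best - cand$value
    if (cand$value < best) { best <- cand$value; theta <- cand$par }
    if (improvement < tol) { converged <- TRUE; break }
  }
  params <- growth_params(exp(theta[1]), exp(theta[2]), theta[3], exp(theta[4]))
  ## contract: never worse than the initial guess
  if (best > rmse_init) {
    params <- init
    best <- rmse_init
    converged <- FALSE
  }
  pred <- po$pred(params)
  structure(list(params = params, rmse = best,
                 r2 = r_squared(pred, po$obs),
                 n_obs = length(po$obs), converged = converged,
                 init = init, rmse_init = rmse_init,
                 datasets = datasets),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("Temperature-response growth model fit\n")
  cat(sprintf("  regimes: %d   observations: %d\n",
              length(x$datasets), x$n_obs))
  cat(sprintf("  pooled RMSE: %.4g g/plant   R^2: %.4f   converged: %s\n",
              x$rmse, x$r2, x$converged))
  print(x$params)
  invisible(x)
}

#' @export
summary.growth_fit <- function(object, ...) {
  res <- residuals(object)
  structure(list(fit = object,
                 resid_summary = summary(res),
                 per_regime = data.frame(
                   regime = vapply(object$datasets, function(d) format(d$regime),
                                   character(1)),
                   temp_K = vapply(object$datasets, `[[`, numeric(1), "temp_K"),
                   n = vapply(object$datasets, function(d) length(d$day),
                              integer(1)),
                   rmse = vapply(object$datasets, function(d)
                     rmse(predict_chamber(d, object$params), d$dry_weight_g),
                     numeric(1)))),
            class = "summary.growth_fit")
}

#' @export
print.summary.growth_fit <- function(x, ...) {
  print(x$fit)
  cat("\nPer-regime RMSE (g/plant):\n")
  print(x$per_regime, row.names = FALSE)
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) {
  unlist(object$params[c("A", "k", "S", "H")])
}

#' Predict dry weights from a growth fit
#'
#' With no `newdata`, returns in-sample predictions at the fitted chamber
#' observation days. `newdata` may be a list with elements `temp_K` and `day`
#' (constant-temperature prediction at `w0`), vectorised over `day`.
#'
#' @param object a `growth_fit`.
#' @param newdata optional list with `temp_K`, `day`, and optionally `w0`.
#' @param ... unused.
#' @export
predict.growth_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    return(unlist(lapply(object$datasets, predict_chamber, object$params)))
  w0 <- if (is.null(newdata$w0)) 0.5 else newdata$w0
  r <- growth_rate(newdata$temp_K, object$params)
  w0 * (1 + r)^newdata$day
}

#' @export
fitted.growth_fit <- function(object, ...) predict(object)

#' @export
residuals.growth_fit <- function(object, ...) {
  unlist(lapply(object$datasets, `[[`, "dry_weight_g")) - fitted(object)
}

#' @export
plot.growth_fit <- function(x, ...) {
  obs <- unlist(lapply(x$datasets, `[[`, "dry_weight_g"))
  pred <- fitted(x)
  graphics::plot(obs, pred, xlab = "observed dry weight (g/plant)",
                 ylab = "predicted dry weight (g/plant)",
                 main = sprintf("Growth model fit (R^2 = %.3f)", x$r2), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
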