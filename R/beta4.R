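#' Four-parameter (scaled) beta distribution
#'
#' Density, distribution function, quantile function and random generation
#' for a beta distribution rescaled to the interval `[minimum, maximum]`.
#' This is the family used for the field-growth-yield input and for the
#' mechanical-harvesting-time input.
#'
#' @param x,q vector of quantiles.
#' @param p vector of probabilities.
#' @param n number of draws.
#' @param alpha,beta shape parameters, > 0.
#' @param minimum,maximum support bounds, `minimum < maximum`.
#' @return `dbeta4` the density, `pbeta4` the CDF, `qbeta4` quantiles,
#'   `rbeta4` random draws.
#' @name beta4
NULL

check_beta4 <- function(alpha, beta, minimum, maximum) {
  if (alpha <= 0 || beta <= 0) stop("beta shapes must be positive", call. = FALSE)
  if (minimum >= maximum) stop("minimum must be below maximum", call. = FALSE)
}

#' @rdname beta4
#' @export
dbeta4 <- function(x, alpha, beta, minimum = 0, maximum = 1) {
  check_beta4(alpha, beta, minimum, maximum)
  stats::dbeta((x - minimum) / (maximum - minimum), alpha, beta) /
    (maximum - minimum)
}

#' @rdname beta4
#' @export
pbeta4 <- function(q, alpha, beta, minimum = 0, maximum = 1) {
  check_beta4(alpha, beta, minimum, maximum)
  stats::pbeta((q - minimum) / (maximum - minimum), alpha, beta)
}

#' @rdname beta4
#' @export
qbeta4 <- function(p, alpha, beta, minimum = 0, maximum = 1) {
  check_beta4(alpha, beta, minimum, maximum)
  minimum + (maximum - minimum) * stats::qbeta(p, alpha, beta)
}

#' @rdname beta4
#' @export
rbeta4 <- function(n, alpha, beta, minimum = 0, maximum = 1) {
  check_beta4(alpha, beta, minimum, maximum)
  minimum + (maximum - minimum) * stats::rbeta(n, alpha, beta)
}

#' Scaled-beta parameter set
#'
#' @param alpha,beta shape parameters, > 0.
#' @param minimum,maximum support bounds, `minimum < maximum`.
#' @return An object of class `scaled_beta`.
#' @examples
#' mean(scaled_beta_params(2.57, 4.80, 0.63, 1)) # ~0.76
#' @export
scaled_beta_params <- function(alpha, beta, minimum, maximum) {
  check_beta4(alpha, beta, minimum, maximum)
  structure(list(alpha = alpha, beta = beta,
                 minimum = minimum, maximum = maximum),
            class = "scaled_beta")
}

#' @export
print.scaled_beta <- function(x, ...) {
  cat(sprintf(
    "Scaled beta: alpha = %.4g, beta = %.4g on [%.4g, %.4g] (mean %.4g)\n",
    x$alpha, x$beta, x$minimum, x$maximum, mean(x)))
  if (!is.null(x$n)) cat(sprintf("  fitted to %d values\n", x$n))
  invisible(x)
}

#' Closed-form mean of a scaled beta distribution
#'
#' `minimum + (maximum - minimum) * alpha / (alpha + beta)`.
#'
#' @param x a [scaled_beta_params()] object.
#' @param ... unused.
#' @return The distribution mean (dimensionless for normalized yields).
#' @export
mean.scaled_beta <- function(x, ...) {
  x$minimum + (x$maximum - x$minimum) * x$alpha / (x$alpha + x$beta)
}

#' Alias for the scaled-beta closed-form mean
#' @inheritParams mean.scaled_beta
#' @param params a [scaled_beta_params()] object.
#' @export
scaled_beta_mean <- function(params) mean.scaled_beta(params)

#' @export
coef.scaled_beta <- function(object, ...) {
  c(alpha = object$alpha, beta = object$beta,
    minimum = object$minimum, maximum = object$maximum)
}

#' @export
simulate.scaled_beta <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  rbeta4(nsim, object$alpha, object$beta, object$minimum, object$maximum)
}

#' Fit a four-parameter beta distribution to normalized yields
#'
#' Bounds first, shapes second: under the normalized-yield convention the
#' upper bound is anchored at 1 (`anchor_max = TRUE`, the default) — the
#' sample maximum is a poor estimator of a soft upper bound when the density
#' vanishes flatly there — while the lower bound is set just below the
#' sample minimum (`margin` of the sample range). Shapes are then estimated
#' by maximum likelihood on the rescaled values via
#' [fitdistrplus::fitdist()]. With `anchor_max = FALSE` the upper bound is
#' set just above the sample maximum instead.
#'
#' @param values normalized yields in (0, 1]; `length(values) >= 10`.
#' @param anchor_max anchor the maximum at 1 (default TRUE).
#' @param margin bound margin as a fraction of the sample range; default 0.005.
#' @return A [scaled_beta_params()] object with extra elements `n` and
#'   `loglik`.
#' @export
fit_scaled_beta <- function(values, anchor_max = TRUE, margin = 0.005) {
  if (length(values) < 10L)
    stop("need at least 10 values to fit a scaled beta", call. = FALSE)
  if (any(values <= 0 | values > 1))
    stop("values must lie in (0, 1]", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("degenerate sample: zero variance", call. = FALSE)
  rng <- max(values) - min(values)
  lo <- min(values) - margin * rng
  hi <- if (anchor_max) 1 else max(values) + margin * rng
  z <- (values - lo) / (hi - lo)
  z <- pmin(pmax(z, 1e-9), 1 - 1e-9)
  fd <- fitdistrplus::fitdist(z, "beta",
                              start = beta_moment_start(z))
  out <- scaled_beta_params(unname(fd$estimate["shape1"]),
                            unname(fd$estimate["shape2"]), lo, hi)
  out$n <- length(values)
  out$loglik <- fd$loglik
  out
}

## method-of-moments starting shapes for the beta MLE
beta_moment_start <- function(z) {
  m <- mean(z); v <- stats::var(z)
  v <- min(v, m * (1 - m) * 0.999)
  common <- m * (1 - m) / v - 1
  list(shape1 = max(m * common, 1e-3), shape2 = max((1 - m) * common, 1e-3))
}
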