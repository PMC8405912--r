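#' Triangular distribution
#'
#' Density, CDF, quantile function and random generation for the triangular
#' distribution on `[minimum, maximum]` with mode `mode`.
#'
#' @param x,q quantiles.
#' @param p probabilities.
#' @param n number of draws.
#' @param minimum,mode,maximum support with `minimum <= mode <= maximum`.
#' @name triangular
NULL

check_tri <- function(minimum, mode, maximum) {
  if (!(minimum <= mode && mode <= maximum) || minimum >= maximum)
    stop("triangular requires minimum <= mode <= maximum, minimum < maximum",
         call. = FALSE)
}

#' @rdname triangular
#' @export
dtri <- function(x, minimum, mode, maximum) {
  check_tri(minimum, mode, maximum)
  out <- numeric(length(x))
  rng <- maximum - minimum
  up <- x >= minimum & x <= mode
  dn <- x > mode & x <= maximum
  if (mode > minimum)
    out[up] <- 2 * (x[up] - minimum) / (rng * (mode - minimum))
  else out[x == minimum] <- 2 / rng
  if (maximum > mode)
    out[dn] <- 2 * (maximum - x[dn]) / (rng * (maximum - mode))
  out
}

#' @rdname triangular
#' @export
ptri <- function(q, minimum, mode, maximum) {
  check_tri(minimum, mode, maximum)
  rng <- maximum - minimum
  out <- numeric(length(q))
  out[q >= maximum] <- 1
  up <- q > minimum & q <= mode
  dn <- q > mode & q < maximum
  if (mode > minimum)
    out[up] <- (q[up] - minimum)^2 / (rng * (mode - minimum))
  if (maximum > mode)
    out[dn] <- 1 - (maximum - q[dn])^2 / (rng * (maximum - mode))
  out
}

#' @rdname triangular
#' @export
qtri <- function(p, minimum, mode, maximum) {
  check_tri(minimum, mode, maximum)
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  rng <- maximum - minimum
  pc <- (mode - minimum) / rng
  out <- numeric(length(p))
  lo <- p <= pc
  out[lo] <- minimum + sqrt(p[lo] * rng * (mode - minimum))
  out[!lo] <- maximum - sqrt((1 - p[!lo]) * rng * (maximum - mode))
  out
}

#' @rdname triangular
#' @export
rtri <- function(n, minimum, mode, maximum) {
  qtri(stats::runif(n), minimum, mode, maximum)
}

## ---- assumption family primitives --------------------------------------
## Each family exposes mean / quantile / cdf on its untruncated form; the
## assumption layer composes truncation via CDF-mapped quantiles.

family_mean <- function(family, pr) {
  switch(family,
    logistic   = pr$location,
    triangular = (pr$minimum + pr$mode + pr$maximum) / 3,
    beta4      = pr$minimum + (pr$maximum - pr$minimum) *
                   pr$alpha / (pr$alpha + pr$beta),
    uniform    = (pr$minimum + pr$maximum) / 2,
    stop("unsupported family: ", family, call. = FALSE))
}

family_quantile <- function(family, pr, p) {
  switch(family,
    logistic   = stats::qlogis(p, pr$location, pr$scale),
    triangular = qtri(p, pr$minimum, pr$mode, pr$maximum),
    beta4      = qbeta4(p, pr$alpha, pr$beta, pr$minimum, pr$maximum),
    uniform    = stats::qunif(p, pr$minimum, pr$maximum),
    stop("unsupported family: ", family, call. = FALSE))
}

family_cdf <- function(family, pr, q) {
  switch(family,
    logistic   = stats::plogis(q, pr$location, pr$scale),
    triangular = ptri(q, pr$minimum, pr$mode, pr$maximum),
    beta4      = pbeta4(q, pr$alpha, pr$beta, pr$minimum, pr$maximum),
    uniform    = stats::punif(q, pr$minimum, pr$maximum),
    stop("unsupported family: ", family, call. = FALSE))
}

family_check <- function(family, pr) {
  ok <- switch(family,
    logistic   = is.finite(pr$location) && pr$scale > 0,
    triangular = { check_tri(pr$minimum, pr$mode, pr$maximum); TRUE },
    beta4      = { check_beta4(pr$alpha, pr$beta, pr$minimum, pr$maximum); TRUE },
    uniform    = pr$minimum < pr$maximum,
    stop("unsupported family: ", family, call. = FALSE))
  if (!isTRUE(ok)) stop("invalid parameters for family ", family, call. = FALSE)
  invisible(TRUE)
}
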