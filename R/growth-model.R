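#' Growth model parameter set
#'
#' Container for the four constants of the temperature-response growth model
#' \deqn{r(T) = \frac{A\,T\,e^{-k/T}}{1 + e^{S - H/T}}}
#' where `T` is absolute temperature (K). Below the optimum the rate follows
#' the Arrhenius law `A T exp(-k/T)`; the logistic denominator models the
#' decline above the optimum through enzyme inactivation. Both `k` and `H`
#' divide the temperature and therefore carry units of kelvin; `S` is
#' dimensionless; `A` has units day^-1 K^-1 so that `r(T)` is a relative
#' growth rate per day (the weight update multiplies it by the current
#' dry weight, see [step_dry_weight()]).
#'
#' @param A pre-exponential coefficient (day^-1 K^-1), > 0.
#' @param k Arrhenius temperature constant (K), > 0.
#' @param S dimensionless inactivation entropy term.
#' @param H inactivation temperature constant (K), > 0.
#' @return An object of class `growth_params`.
#' @seealso [default_growth_params()], [growth_rate()]
#' @examples
#' p <- growth_params(A = 0.56, k = 1992, S = 27, H = 8250)
#' growth_rate(297.15, p)
#' @export
growth_params <- function(A, k, S, H) {
  vals <- c(A = A, k = k, S = S, H = H)
  if (!all(is.finite(vals)))
    stop("growth parameters must all be finite", call. = FALSE)
  if (A < 0 || k <= 0 || H <= 0)
    stop("growth parameters require A >= 0, k > 0, H > 0", call. = FALSE)
  structure(list(A = A, k = k, S = S, H = H), class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat("Temperature-response growth parameters:\n")
  cat(sprintf("  A = %g day^-1 K^-1   k = %g K   S = %g   H = %g K\n",
              x$A, x$k, x$S, x$H))
  invisible(x)
}

#' Default growth parameters
#'
#' A calibrated parameter set used as the truth for the synthetic-data
#' generators and as a sensible default throughout the package. It is
#' calibrated so that (i) the optimum of `r(T)` falls at ~295 K (22 degC),
#' inside the 18.5--28.5 degC optimal range reported for tobacco, and
#' (ii) a seedling of 0.5 g/plant dry weight grows to ~21 g/plant over a
#' 27-day window at a subtropical mean temperature of 297 K. Constants
#' reported in the literature for this functional form do not yield a usable
#' relative rate at these magnitudes (see the methods vignette), hence this
#' package-level calibration.
#'
#' @return A `growth_params` object.
#' @export
default_growth_params <- function() {
  growth_params(A = 0.55914, k = 1992, S = 27, H = 8250)
}

#' Weighted day temperature for a day/night chamber regime
#'
#' Growth chambers hold a high (day) temperature for `h_high` hours and a low
#' (night) temperature for `h_low` hours; daily model steps use the
#' hour-weighted average `(h_high * high + h_low * low) / 24`.
#'
#' @param high,low high and low temperatures (K).
#' @param h_high,h_low hours per day at the high and low temperature; must sum
#'   to 24. Defaults 9 and 15.
#' @return Weighted temperature (K); vectorised over `high`/`low`.
#' @examples
#' weighted_day_temperature(303.15, 293.15) # 9 h warm, 15 h cool
#' @export
weighted_day_temperature <- function(high, low, h_high = 9, h_low = 15) {
  if (!isTRUE(all.equal(h_high + h_low, 24)))
    stop("invalid design: hours at high and low temperature must sum to 24",
         call. = FALSE)
  if (!all(is.finite(high)) || !all(is.finite(low)))
    stop("temperatures must be finite", call. = FALSE)
  (h_high * high + h_low * low) / 24
}

#' Temperature-dependent relative growth rate
#'
#' Evaluates `r(T) = A T exp(-k/T) / (1 + exp(S - H/T))` (day^-1).
#'
#' @param temp_K absolute temperature (K), > 0; vectorised.
#' @param params a [growth_params()] object.
#' @return Relative growth rate (day^-1), strictly positive when `A > 0`.
#' @export
growth_rate <- function(temp_K, params = default_growth_params()) {
  stopifnot(inherits(params, "growth_params"))
  if (any(!is.finite(temp_K)) || any(temp_K <= 0))
    stop("temperature must be positive (kelvin)", call. = FALSE)
  params$A * temp_K * exp(-params$k / temp_K) /
    (1 + exp(params$S - params$H / temp_K))
}

#' One explicit-Euler dry-weight step
#'
#' `W1 = W0 + W0 * r(T) * dt`: the rate is relative, so the increment is
#' proportional to the current weight.
#'
#' @param w0 dry weight at the start of the step (g/plant), > 0.
#' @param temp_K temperature over the step (K).
#' @param dt step length (day); 1 for daily steps, 1/24 for hourly.
#' @param params a [growth_params()] object.
#' @return Dry weight after the step (g/plant).
#' @export
step_dry_weight <- function(w0, temp_K, dt = 1, params = default_growth_params()) {
  if (any(!is.finite(w0)) || any(w0 <= 0))
    stop("initial dry weight must be positive", call. = FALSE)
  if (any(dt <= 0)) stop("time step must be positive", call. = FALSE)
  w0 * (1 + growth_rate(temp_K, params) * dt)
}

#' Simulate a dry-weight trajectory over a temperature series
#'
#' Applies [step_dry_weight()] sequentially over a time-ordered temperature
#' series. With hourly temperatures use `dt = 1/24`.
#'
#' @param temps time-ordered temperatures (K), one per step. May be empty, in
#'   which case the trajectory is just `w0`.
#' @param w0 initial dry weight (g/plant).
#' @param params a [growth_params()] object.
#' @param dt step length (day) matching the sampling interval of `temps`.
#' @return Numeric vector of length `length(temps) + 1`; first element `w0`.
#' @export
simulate_trajectory <- function(temps, w0 = 0.5, params = default_growth_params(),
                                dt = 1 / 24) {
  if (is.null(temps)) stop("temperature series must be supplied", call. = FALSE)
  if (any(!is.finite(w0)) || w0 <= 0)
    stop("initial dry weight must be positive", call. = FALSE)
  if (length(temps) == 0L) return(w0)
  r <- growth_rate(temps, params)
  w0 * cumprod(c(1, 1 + r * dt))
}

#' Root mean squared error
#'
#' @param pred model predictions.
#' @param obs observations; same length as `pred`.
#' @return `sqrt(mean((pred - obs)^2))` (g/plant when inputs are weights).
#' @export
rmse <- function(pred, obs) {
  if (length(pred) != length(obs) || length(pred) == 0L)
    stop("pred and obs must have equal, non-zero length", call. = FALSE)
  sqrt(mean((pred - obs)^2))
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`; equals 1 for a perfect fit and may be negative for
#' fits worse than the observation mean.
#'
#' @inheritParams rmse
#' @return Dimensionless R^2.
#' @export
r_squared <- function(pred, obs) {
  if (length(pred) != length(obs) || length(obs) < 2L)
    stop("need at least two paired observations", call. = FALSE)
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0)
    stop("R^2 undefined: observations have zero variance", call. = FALSE)
  1 - sum((pred - obs)^2) / ss_tot
}
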