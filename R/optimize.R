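#' Decision specification for optimization under uncertainty
#'
#' The retrofitting case treats the CEX column diameter as a scalar decision
#' variable evaluated over a finite candidate grid.
#'
#' @param name decision name; default `"cex_column_diameter"`.
#' @param candidates candidate values (m), all > 0, non-empty.
#' @param forecast forecast to optimize; default `"irr_after_tax"`.
#' @param statistic summary statistic of the forecast sample: `"mean"`,
#'   `"median"` or `"quantile"`.
#' @param direction `"maximize"` (default) or `"minimize"`.
#' @param prob quantile level when `statistic = "quantile"`.
#' @return An object of class `decision_spec`.
#' @export
decision_spec <- function(name = "cex_column_diameter",
                          candidates = seq(1.0, 2.2, by = 0.2),
                          forecast = "irr_after_tax",
                          statistic = c("mean", "median", "quantile"),
                          direction = c("maximize", "minimize"),
                          prob = 0.5) {
  if (length(candidates) == 0L || any(candidates <= 0))
    stop("candidates must be a non-empty positive grid", call. = FALSE)
  structure(list(name = name, candidates = candidates, forecast = forecast,
                 statistic = match.arg(statistic),
                 direction = match.arg(direction), prob = prob),
            class = "decision_spec")
}

#' Grid-search optimization under uncertainty with common random numbers
#'
#' Evaluates every candidate value of the decision variable on the *same*
#' seeded trial-input draws (common random numbers), so candidate-to-
#' candidate differences reflect the decision alone, and selects the
#' candidate with the best estimated objective.
#'
#' @param spec a [decision_spec()].
#' @param plan a [simulation_plan()]; its seed drives the single common
#'   input draw. Only the first price is used unless the plan has one price.
#' @param registry an `assumption_registry`.
#' @param correlation optional [correlation_spec()].
#' @param equipment base [equipment_spec()]; the decision field is
#'   overwritten per candidate.
#' @param econ an [econ_config()].
#' @return An object of class `optimization_result`: `table` (per-candidate
#'   `candidate`, `objective`, `se`, `n`, `n_failed`), `selected` (the
#'   argbest candidate), `spec`, `seed`.
#' @export
optimize_decision <- function(spec, plan, registry = default_registry(),
                              correlation = NULL,
                              equipment = equipment_spec(),
                              econ = econ_config()) {
  stopifnot(inherits(spec, "decision_spec"), inherits(plan, "simulation_plan"))
  price <- plan$prices[1]
  inputs <- sample_trials(registry, correlation, plan$n_trials, plan$seed)
  rows <- lapply(spec$candidates, function(cand) {
    eq <- equipment
    eq[[spec$name]] <- cand
    res <- tryCatch(run_tea(inputs, eq, econ, price), error = function(e) e)
    if (inherits(res, "error"))
      return(data.frame(candidate = cand, objective = NA_real_,
                        se = NA_real_, n = 0L, n_failed = plan$n_trials,
                        message = conditionMessage(res)))
    v <- res[[spec$forecast]]
    v_ok <- v[!is.na(v)]
    obj <- switch(spec$statistic,
                  mean = mean(v_ok),
                  median = stats::median(v_ok),
                  quantile = unname(stats::quantile(v_ok, spec$prob)))
    se <- stats::sd(v_ok) / sqrt(length(v_ok))
    data.frame(candidate = cand, objective = obj, se = se,
               n = length(v_ok), n_failed = sum(is.na(v)), message = "")
  })
  table <- do.call(rbind, rows)
  if (all(is.na(table$objective)))
    stop("all candidates infeasible:\n",
         paste(sprintf("  %g: %s", table$candidate, table$message),
               collapse = "\n"), call. = FALSE)
  obj <- table$objective
  best <- if (spec$direction == "maximize") which.max(obj) else which.min(obj)
  structure(list(table = table, selected = table$candidate[best],
                 spec = spec, seed = plan$seed, n_trials = plan$n_trials),
            class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf("Decision optimization: %s %s of %s over %d candidates (n = %d, seed %d)\n",
              x$spec$direction, x$spec$statistic, x$spec$forecast,
              nrow(x$table), x$n_trials, x$seed))
  print(x$table[, c("candidate", "objective", "se", "n", "n_failed")],
        row.names = FALSE)
  cat(sprintf("selected: %g\n", x$selected))
  invisible(x)
}
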