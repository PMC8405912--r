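#' Simulation plan
#'
#' @param n_trials Monte Carlo trials per selling price, >= 1. The published
#'   convention is 20,000 trials for each of three selling prices, so that
#'   profitability forecasts are analysed per price (n = 20,000) and process
#'   forecasts pooled across prices (n = 60,000).
#' @param prices selling prices ($/g), all > 0.
#' @param seed integer seed of the scenario's single pseudo-random stream.
#' @param scenario scenario label, e.g. `"base"` or `"oversized_1.5"`.
#' @return An object of class `simulation_plan`.
#' @export
simulation_plan <- function(n_trials = 20000, prices = c(10, 20, 40),
                            seed = 1, scenario = "base") {
  if (n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  if (length(prices) < 1 || any(prices <= 0))
    stop("need at least one positive price", call. = FALSE)
  structure(list(n_trials = as.integer(n_trials), prices = prices,
                 seed = as.integer(seed), scenario = scenario),
            class = "simulation_plan")
}

#' Run the Monte Carlo trial loop
#'
#' Draws one trial-input matrix per scenario (a single seeded stream) and
#' evaluates the surrogate techno-economic model once per selling price,
#' reusing identical sampled inputs across prices: the price enters the
#' economics only, so process-related forecasts (annual throughput, purity)
#' are price-invariant and may be pooled across prices.
#'
#' @param plan a [simulation_plan()].
#' @param registry an `assumption_registry`; default [default_registry()].
#' @param correlation optional [correlation_spec()].
#' @param equipment an [equipment_spec()].
#' @param econ an [econ_config()].
#' @return A data frame of class `tea_trials` with `n_trials * length(prices)`
#'   rows: `scenario`, `price_usd_g`, `trial`, the nine sampled inputs, the
#'   four forecasts (`irr_after_tax`, `cogs_usd_g`, `annual_throughput_kg`,
#'   `purity`), `irr_defined`, and clamp flags. Trials whose IRR is undefined
#'   (no cash-flow sign change) are retained with `NA` and flagged, never
#'   dropped.
#' @examples
#' tr <- run_simulation(simulation_plan(n_trials = 50, prices = 20, seed = 1))
#' nrow(tr)
#' @export
run_simulation <- function(plan, registry = default_registry(),
                           correlation = NULL,
                           equipment = equipment_spec(),
                           econ = econ_config()) {
  stopifnot(inherits(plan, "simulation_plan"))
  inputs <- sample_trials(registry, correlation, plan$n_trials, plan$seed)
  out <- lapply(plan$prices, function(price) {
    e <- run_tea(inputs, equipment, econ, price)
    cbind(data.frame(scenario = plan$scenario, price_usd_g = price,
                     trial = seq_len(plan$n_trials)),
          as.data.frame(inputs),
          data.frame(irr_after_tax = e$irr_after_tax,
                     irr_defined = e$irr_defined,
                     cogs_usd_g = e$cogs_usd_g,
                     annual_throughput_kg = e$annual_throughput_kg,
                     purity = e$purity,
                     clamped_field = e$clamped_field,
                     clamped_cex = e$clamped_cex))
  })
  records <- do.call(rbind, out)
  rownames(records) <- NULL
  n_undef <- sum(!records$irr_defined)
  attr(records, "plan") <- plan
  attr(records, "n_irr_undefined") <- n_undef
  if (n_undef > 0)
    message(n_undef, " trial(s) with undefined IRR retained with NA")
  class(records) <- c("tea_trials", "data.frame")
  records
}

#' @export
print.tea_trials <- function(x, ...) {
  plan <- attr(x, "plan")
  cat(sprintf("Monte Carlo trials: %d rows (%d trials x %d price(s)), scenario '%s'\n",
              nrow(x), plan$n_trials, length(plan$prices), plan$scenario))
  cat(sprintf("  IRR undefined: %d; field clamps: %d; CEX clamps: %d\n",
              sum(!x$irr_defined), sum(x$clamped_field), sum(x$clamped_cex)))
  invisible(x)
}

#' Split trial records into profitability and process forecast tables
#'
#' Profitability forecasts (IRR after tax, COGS) depend on the selling price
#' and are grouped per price (`n_trials` rows each); process forecasts
#' (annual throughput, purity) are price-invariant and pooled across prices.
#'
#' @param records a `tea_trials` data frame from [run_simulation()].
#' @return A list with `profitability` (list of data frames keyed by price,
#'   columns `trial`, `irr_after_tax`, `cogs_usd_g`) and `process` (one
#'   pooled data frame, columns `price_usd_g`, `trial`,
#'   `annual_throughput_kg`, `purity`).
#' @export
split_forecasts <- function(records) {
  if (nrow(records) == 0L) stop("no trial records", call. = FALSE)
  prices <- unique(records$price_usd_g)
  profitability <- lapply(prices, function(p) {
    sub <- records[records$price_usd_g == p,
                   c("trial", "irr_after_tax", "irr_defined", "cogs_usd_g")]
    rownames(sub) <- NULL
    sub
  })
  names(profitability) <- as.character(prices)
  process <- records[, c("price_usd_g", "trial", "annual_throughput_kg",
                         "purity")]
  rownames(process) <- NULL
  list(profitability = profitability, process = process)
}
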