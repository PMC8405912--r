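#' Clamp a quantity to an equipment capacity ("effective value")
#'
#' Under fixed equipment sizing, stochastic excess stream volume or product
#' mass cannot be absorbed by the facility; the affected quantity is reduced
#' to the effective value at the rated capacity.
#'
#' @param value quantity (vectorised).
#' @param cap rated capacity, > 0.
#' @return A list with `value = pmin(value, cap)` and `clamped`, a logical
#'   flag per element, `TRUE` iff the cap was binding.
#' @examples
#' effective_clamp(120, 100)
#' @export
effective_clamp <- function(value, cap) {
  if (any(cap <= 0)) stop("capacity must be positive", call. = FALSE)
  list(value = pmin(value, cap), clamped = value > cap)
}

#' Equipment specification for the fixed-size facility
#'
#' Rated per-batch capacities. All capacities scale multiplicatively with
#' `oversize_factor` (the facility-oversizing scenario family); the cation
#' exchange column's product-mass capacity additionally scales with its
#' cross-sectional area (`cex_loading_kg_m2 * pi d^2 / 4`).
#'
#' @param max_field_volume_L rated field-extract stream volume (L/batch).
#' @param cex_column_diameter CEX column diameter (m); the retrofit decision
#'   variable.
#' @param cex_loading_kg_m2 product-mass capacity per m2 of column
#'   cross-section (kg/m2).
#' @param pf_area_m2,tff_area_m2 installed membrane areas (m2).
#' @param oversize_factor capacity scale factor, >= 1 for oversizing
#'   scenarios; 1 is the base case.
#' @return An object of class `tea_equipment`.
#' @export
equipment_spec <- function(max_field_volume_L = 190000,
                           cex_column_diameter = 1.6,
                           cex_loading_kg_m2 = 80,
                           pf_area_m2 = 200,
                           tff_area_m2 = 400,
                           oversize_factor = 1) {
  vals <- c(max_field_volume_L, cex_column_diameter, cex_loading_kg_m2,
            pf_area_m2, tff_area_m2, oversize_factor)
  if (any(vals <= 0)) stop("all capacities must be positive", call. = FALSE)
  structure(list(max_field_volume_L = max_field_volume_L,
                 cex_column_diameter = cex_column_diameter,
                 cex_loading_kg_m2 = cex_loading_kg_m2,
                 pf_area_m2 = pf_area_m2, tff_area_m2 = tff_area_m2,
                 oversize_factor = oversize_factor),
            class = "tea_equipment")
}

## rated product-mass capacity of the CEX column (kg/batch)
cex_capacity_kg <- function(equipment) {
  equipment$oversize_factor * equipment$cex_loading_kg_m2 *
    pi * equipment$cex_column_diameter^2 / 4
}

#' Economic and process configuration for the surrogate facility model
#'
#' The surrogate's structure — stage list, volume ratios, and a cost model of
#' capital expenditure plus fixed and throughput-proportional operating cost
#' with straight-line depreciation and a single tax rate — is this package's
#' own transparent design; every constant is a config field. Defaults sketch
#' an ultra-large field-grown facility and are placeholders, not estimates of
#' any published facility.
#'
#' @param nominal_biomass_kg nominal harvested fresh-weight biomass
#'   (kg FW/batch) at a field-growth yield of 1.
#' @param extraction_ratio_L_kg extract volume per kg biomass (L/kg FW).
#' @param pf_volume_ratio,tff_volume_ratio stage volume carried forward as a
#'   fraction of the incoming volume.
#' @param initial_purity product purity of the crude extract (fraction).
#' @param pf_enrichment,tff_enrichment base purity enrichment (odds
#'   multipliers) of the clarification and UF/DF stages.
#' @param cex_enrichment CEX purity enrichment at the base-case recovery.
#' @param cex_recovery_base base-case CEX recovery used by the
#'   purity--recovery trade-off.
#' @param cex_purity_tradeoff exponent of the recovery--purity trade-off
#'   (higher recovery, broader peak cut, lower enrichment); 0 disables it.
#' @param harvest_handling_h,cex_time_h,turnaround_h fixed stage times (h).
#' @param operating_days annual operating window (day/yr); default 330.
#' @param base_capex_usd capital expenditure excluding the CEX column ($).
#' @param cex_cost_usd_m2 installed CEX cost per m2 cross-section ($/m2).
#' @param biomass_cost_usd_kg field biomass production cost ($/kg FW).
#' @param field_time_cost_usd_day field operations cost per day of growth
#'   time ($/day, per batch).
#' @param consumables_usd_batch single-use consumables per batch ($).
#' @param utilities_usd_L utilities cost per litre of crude extract ($/L).
#' @param labor_usd_yr annual labor ($/yr).
#' @param maintenance_frac,insurance_frac annual maintenance and insurance as
#'   fractions of capex.
#' @param resin_cost_usd_m2_yr annual CEX resin replacement ($/m2/yr).
#' @param depreciation_years straight-line depreciation period (yr).
#' @param tax_rate corporate tax rate (fraction).
#' @param project_years project horizon for the cash-flow series (yr).
#' @return An object of class `tea_econ`.
#' @export
econ_config <- function(nominal_biomass_kg = 1e5,
                        extraction_ratio_L_kg = 2,
                        pf_volume_ratio = 0.9,
                        tff_volume_ratio = 0.05,
                        initial_purity = 0.05,
                        pf_enrichment = 3,
                        tff_enrichment = 2,
                        cex_enrichment = 10,
                        cex_recovery_base = 0.90,
                        cex_purity_tradeoff = 0.5,
                        harvest_handling_h = 6,
                        cex_time_h = 12,
                        turnaround_h = 24,
                        operating_days = 330,
                        base_capex_usd = 550e6,
                        cex_cost_usd_m2 = 25e6,
                        biomass_cost_usd_kg = 0.5,
                        field_time_cost_usd_day = 2000,
                        consumables_usd_batch = 2e5,
                        utilities_usd_L = 0.01,
                        labor_usd_yr = 8e6,
                        maintenance_frac = 0.03,
                        insurance_frac = 0.007,
                        resin_cost_usd_m2_yr = 4e5,
                        depreciation_years = 10,
                        tax_rate = 0.25,
                        project_years = 20) {
  out <- as.list(environment())
  if (any(unlist(out) <= 0)) stop("all config constants must be positive",
                                  call. = FALSE)
  structure(out, class = "tea_econ")
}

#' Run the surrogate batch mass balance
#'
#' Field to purified product, vectorised over trials: harvested biomass is
#' `nominal_biomass_kg * field_growth_yield` with the field-stage stream
#' volume clamp applied; crude product is biomass times expression level;
#' recoveries multiply through clarification (plate & frame), UF/DF (TFF) and
#' CEX, with the product-mass clamp applied at the CEX column. Purity
#' compounds odds-multiplicative enrichment factors per purification stage,
#' with a configurable recovery--purity trade-off at the CEX step.
#'
#' @param inputs a data frame (or `trial_inputs`) with one row per trial and
#'   the nine columns of [default_registry()].
#' @param equipment an [equipment_spec()].
#' @param econ an [econ_config()].
#' @return A list of class `batch_result`, each element vectorised over
#'   trials: `biomass_kg`, `volume_L` (crude extract, post-clamp),
#'   `product_kg` (named matrix of stage product masses), `final_product_kg`,
#'   `purity`, and logical clamp flags `clamped_field`, `clamped_cex`.
#' @export
run_batch <- function(inputs, equipment, econ) {
  stopifnot(inherits(equipment, "tea_equipment"), inherits(econ, "tea_econ"))
  need <- c("field_growth_yield", "expression_level", "pf_recovery",
            "tff_recovery", "cex_recovery")
  miss <- setdiff(need, names(inputs))
  if (length(miss)) stop("inputs missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  frac_cols <- c("field_growth_yield", "pf_recovery", "tff_recovery",
                 "cex_recovery")
  for (cc in frac_cols)
    if (any(inputs[[cc]] <= 0 | inputs[[cc]] > 1))
      stop("stage '", cc, "': fractions must lie in (0, 1]", call. = FALSE)
  if (any(inputs$expression_level <= 0))
    stop("stage 'expression': expression level must be positive",
         call. = FALSE)

  biomass <- econ$nominal_biomass_kg * inputs$field_growth_yield
  vol_raw <- biomass * econ$extraction_ratio_L_kg
  vc <- effective_clamp(vol_raw, equipment$oversize_factor *
                                   equipment$max_field_volume_L)
  ## a binding field volume clamp reduces the effective harvested biomass
  biomass_eff <- vc$value / econ$extraction_ratio_L_kg
  crude <- biomass_eff * inputs$expression_level / 1000   # kg product
  after_pf  <- crude * inputs$pf_recovery
  after_tff <- after_pf * inputs$tff_recovery
  cex_raw   <- after_tff * inputs$cex_recovery
  pc <- effective_clamp(cex_raw, cex_capacity_kg(equipment))
  if (any(pc$value > after_tff + 1e-12))
    stop("stage 'cex': product mass increased through a recovery stage",
         call. = FALSE)

  odds <- econ$initial_purity / (1 - econ$initial_purity)
  e_cex <- econ$cex_enrichment *
    ((1 - inputs$cex_recovery) / (1 - econ$cex_recovery_base))^
      econ$cex_purity_tradeoff
  odds_final <- odds * econ$pf_enrichment * econ$tff_enrichment * e_cex
  purity <- odds_final / (1 + odds_final)

  product <- cbind(crude = crude, pf = after_pf, tff = after_tff,
                   cex = pc$value)
  structure(list(biomass_kg = biomass_eff, volume_L = vc$value,
                 product_kg = product, final_product_kg = pc$value,
                 purity = purity,
                 clamped_field = vc$clamped, clamped_cex = pc$clamped),
            class = "batch_result")
}

#' Batch duration
#'
#' Sum of stage times (h): mechanical harvesting plus fixed handling,
#' filtration stage times `volume / (flux * area)` for plate & frame and
#' TFF, a fixed CEX cycle, and turnaround. Field growth happens in staggered
#' parallel plantings and does not occupy the processing train.
#'
#' @inheritParams run_batch
#' @param batch a [run_batch()] result.
#' @return Duration per trial (h).
#' @export
batch_duration <- function(inputs, batch, equipment, econ) {
  if (any(inputs$pf_flux <= 0) || any(inputs$tff_flux <= 0))
    stop("fluxes must be positive", call. = FALSE)
  if (equipment$pf_area_m2 <= 0 || equipment$tff_area_m2 <= 0)
    stop("config error: membrane area must be positive", call. = FALSE)
  pf_vol  <- batch$volume_L
  tff_vol <- batch$volume_L * econ$pf_volume_ratio
  t_pf  <- pf_vol  / (inputs$pf_flux  * equipment$pf_area_m2 *
                        equipment$oversize_factor)
  t_tff <- tff_vol / (inputs$tff_flux * equipment$tff_area_m2 *
                        equipment$oversize_factor)
  inputs$harvest_time + econ$harvest_handling_h + t_pf + t_tff +
    econ$cex_time_h + econ$turnaround_h
}

## internal: NPV of a cash-flow vector cf[1] at t=0
npv <- function(rate, cf) sum(cf / (1 + rate)^(seq_along(cf) - 1))

#' Internal rate of return of a cash-flow series
#'
#' Root of the NPV over `(-0.99, 10)` by bracketed root-finding (bisection-
#' safe [stats::uniroot()], tolerance 1e-12 on the rate). Returns `NA` with a
#' warning-free flag when the cash flows admit no sign change.
#'
#' @param cf cash-flow vector, `cf[1]` at time zero.
#' @return IRR (fraction/yr) or `NA_real_` if undefined.
#' @examples
#' irr(c(-100, 110)) # 0.10
#' @export
irr <- function(cf) {
  f <- function(r) npv(r, cf)
  lo <- -0.99; hi <- 10
  flo <- f(lo); fhi <- f(hi)
  if (!is.finite(flo) || !is.finite(fhi) || sign(flo) == sign(fhi))
    return(NA_real_)
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

#' Annual economics of the surrogate facility
#'
#' Computes batches per year (`floor(operating hours / duration)`), annual
#' throughput, the itemized annual operating cost by facility section, cost
#' of goods sold, and the after-tax internal rate of return of the project
#' cash-flow series (year 0 capex out, `project_years` equal operating
#' years). Depreciation (straight-line over `depreciation_years`) is carried
#' as an operating-cost item — so COGS is fully loaded — and is added back
#' in the cash flows, acting only through the tax shield.
#'
#' @inheritParams batch_duration
#' @param duration_h batch duration per trial (h), from [batch_duration()].
#' @param price selling price ($/g).
#' @param detail if `TRUE`, include the per-trial cost breakdown (list of
#'   section -> item matrices).
#' @return A list of class `econ_result`, vectorised over trials:
#'   `irr_after_tax` (fraction/yr, `NA` when undefined), `irr_defined`,
#'   `cogs_usd_g`, `annual_throughput_kg`, `n_batches`, `capex_usd`,
#'   `annual_cost_usd`, `purity`, and optionally `breakdown`.
#' @export
economics <- function(batch, duration_h, price, equipment, econ,
                      detail = FALSE) {
  if (any(price <= 0)) stop("price must be positive", call. = FALSE)
  hours_yr <- econ$operating_days * 24
  n_batches <- floor(hours_yr / duration_h)
  annual_product_kg <- batch$final_product_kg * n_batches
  annual_product_g <- annual_product_kg * 1000

  area <- pi * equipment$cex_column_diameter^2 / 4 * equipment$oversize_factor
  capex <- econ$base_capex_usd * equipment$oversize_factor +
    econ$cex_cost_usd_m2 * area
  depreciation <- capex / econ$depreciation_years

  ## annual cost items by facility section
  field_biomass <- econ$biomass_cost_usd_kg * batch$biomass_kg * n_batches
  field_time <- econ$field_time_cost_usd_day *
    (if ("field_growth_time" %in% names(attributes(batch)))
       attr(batch, "field_growth_time") else 42) * n_batches
  clar_consumables <- econ$consumables_usd_batch * 0.5 * n_batches
  clar_utilities <- econ$utilities_usd_L * batch$volume_L * n_batches
  tff_consumables <- econ$consumables_usd_batch * 0.3 * n_batches
  cex_consumables <- econ$consumables_usd_batch * 0.2 * n_batches
  cex_resin <- econ$resin_cost_usd_m2_yr * area + 0 * n_batches
  labor <- econ$labor_usd_yr + 0 * n_batches
  maintenance <- econ$maintenance_frac * capex + 0 * n_batches
  insurance <- econ$insurance_frac * capex + 0 * n_batches
  depr_item <- depreciation + 0 * n_batches

  breakdown <- list(
    field = list(biomass = field_biomass, field_operations = field_time),
    clarification = list(consumables = clar_consumables,
                         utilities = clar_utilities),
    tff = list(consumables = tff_consumables),
    cex = list(consumables = cex_consumables, resin = cex_resin),
    general = list(labor = labor, maintenance = maintenance,
                   insurance = insurance, depreciation = depr_item))
  annual_cost <- Reduce(`+`, unlist(breakdown, recursive = FALSE))

  cogs <- annual_cost / annual_product_g
  revenue <- price * annual_product_g
  ebit <- revenue - annual_cost                 # annual_cost includes depr
  tax <- econ$tax_rate * pmax(ebit, 0)
  cf_op <- ebit + depreciation - tax            # add back non-cash depr

  irr_v <- vapply(seq_along(cf_op), function(i)
    irr(c(-capex, rep(cf_op[i], econ$project_years))), numeric(1))

  out <- list(irr_after_tax = irr_v, irr_defined = !is.na(irr_v),
              cogs_usd_g = cogs, annual_throughput_kg = annual_product_kg,
              n_batches = n_batches, capex_usd = capex,
              annual_cost_usd = annual_cost, purity = batch$purity)
  if (detail) out$breakdown <- breakdown
  structure(out, class = "econ_result")
}

#' Deterministic re-run of one trial with a full cost breakdown
#'
#' Re-evaluates the surrogate for a single set of trial inputs and returns
#' the itemized annual cost by facility section (as generated for the trials
#' that yield the minimum, mean and maximum IRR).
#'
#' @param inputs one-row data frame (or single-row subset of a
#'   `trial_inputs`) with the nine registry columns.
#' @param equipment an [equipment_spec()].
#' @param econ an [econ_config()].
#' @param price selling price ($/g).
#' @return An `econ_result` with `breakdown` attached.
#' @export
cost_breakdown_at <- function(inputs, equipment, econ, price) {
  stopifnot(nrow(inputs) == 1L)
  b <- run_batch(inputs, equipment, econ)
  attr(b, "field_growth_time") <- inputs$field_growth_time
  d <- batch_duration(inputs, b, equipment, econ)
  economics(b, d, price, equipment, econ, detail = TRUE)
}

#' Evaluate the full surrogate for a set of trials
#'
#' Convenience wrapper chaining [run_batch()], [batch_duration()] and
#' [economics()].
#'
#' @inheritParams run_batch
#' @param price selling price ($/g).
#' @return An `econ_result` with clamp flags `clamped_field`/`clamped_cex`
#'   attached.
#' @export
run_tea <- function(inputs, equipment, econ, price) {
  b <- run_batch(inputs, equipment, econ)
  attr(b, "field_growth_time") <- inputs$field_growth_time
  d <- batch_duration(inputs, b, equipment, econ)
  e <- economics(b, d, price, equipment, econ)
  e$clamped_field <- b$clamped_field
  e$clamped_cex <- b$clamped_cex
  e$duration_h <- d
  e
}
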