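test_that("effective clamping caps values and flags the cap", {
  expect_equal(effective_clamp(90, 100), list(value = 90, clamped = FALSE))
  expect_equal(effective_clamp(120, 100), list(value = 100, clamped = TRUE))
  ## idempotent
  once <- effective_clamp(120, 100)
  expect_equal(effective_clamp(once$value, 100)$value, once$value)
  expect_false(effective_clamp(once$value, 100)$clamped)
  expect_error(effective_clamp(1, -1), "positive")
})

base_inputs <- function(...) {
  x <- registry_base(default_registry())
  over <- list(...)
  x[names(over)] <- over
  x
}

test_that("the batch mass balance multiplies recoveries through the chain", {
  eq <- equipment_spec(oversize_factor = 100)   # no clamps
  ec <- econ_config()
  lossless <- base_inputs(field_growth_yield = 1, pf_recovery = 1,
                          tff_recovery = 1, cex_recovery = 1)
  b <- run_batch(lossless, eq, ec)
  expect_equal(b$final_product_kg,
               ec$nominal_biomass_kg * lossless$expression_level / 1000)
  x <- base_inputs(field_growth_yield = 1, pf_recovery = 0.9,
                   tff_recovery = 0.9, cex_recovery = 0.9)
  b9 <- run_batch(x, eq, ec)
  expect_equal(b9$final_product_kg, 0.729 * b$final_product_kg)
  ## product mass is non-increasing through the stages
  expect_true(all(diff(as.numeric(b9$product_kg[1, ])) <= 1e-12))
  expect_true(b9$purity > 0 && b9$purity <= 1)
})

test_that("clamps bind at the field and CEX stages and set flags", {
  ec <- econ_config()
  eq <- equipment_spec(max_field_volume_L = 0.8 * ec$nominal_biomass_kg *
                         ec$extraction_ratio_L_kg)
  b <- run_batch(base_inputs(field_growth_yield = 0.99), eq, ec)
  expect_true(b$clamped_field)
  expect_equal(b$volume_L, eq$max_field_volume_L)
  expect_equal(b$biomass_kg, 0.8 * ec$nominal_biomass_kg)
  ## CEX product-mass cap
  eq2 <- equipment_spec(cex_column_diameter = 0.5)
  b2 <- run_batch(base_inputs(expression_level = 3), eq2, ec)
  expect_true(b2$clamped_cex)
  expect_equal(b2$final_product_kg, 80 * pi * 0.5^2 / 4)
  ## with a large oversize factor nothing clamps over many trials
  x <- sample_trials(default_registry(), n = 20000, seed = 77)
  b3 <- run_batch(x, equipment_spec(oversize_factor = 10), ec)
  expect_equal(sum(b3$clamped_field) + sum(b3$clamped_cex), 0L)
})

test_that("batch duration decomposes into stage times", {
  eq <- equipment_spec()
  ec <- econ_config()
  x <- base_inputs()
  b <- run_batch(x, eq, ec)
  d <- batch_duration(x, b, eq, ec)
  t_pf <- b$volume_L / (x$pf_flux * eq$pf_area_m2)
  t_tff <- b$volume_L * ec$pf_volume_ratio / (x$tff_flux * eq$tff_area_m2)
  expect_equal(d, x$harvest_time + ec$harvest_handling_h + t_pf + t_tff +
                 ec$cex_time_h + ec$turnaround_h)
  ## doubling the TFF flux halves the TFF stage time
  x2 <- base_inputs(tff_flux = 2 * x$tff_flux)
  expect_equal(batch_duration(x2, b, eq, ec), d - t_tff / 2)
  ## harvest time adds linearly; total dominates each stage
  x3 <- base_inputs(harvest_time = x$harvest_time + 5)
  expect_equal(batch_duration(x3, b, eq, ec), d + 5)
  expect_gte(d, max(t_pf, t_tff, x$harvest_time))
  expect_error(batch_duration(base_inputs(pf_flux = 0), b, eq, ec),
               "positive")
})

test_that("IRR solves the NPV root to high precision", {
  expect_equal(irr(c(-100, 110)), 0.10, tolerance = 1e-9)
  expect_equal(irr(c(-100, 0, 121)), 0.10, tolerance = 1e-9)
  expect_true(is.na(irr(c(-100, -5, -5))))
  set.seed(19)
  for (i in 1:10) {
    cf <- c(-runif(1, 50, 500), runif(10, 0, 80))
    r <- irr(cf)
    if (!is.na(r))
      expect_lt(abs(sum(cf / (1 + r)^(0:10))), 1e-6 * abs(cf[1]))
  }
})

test_that("economics reconciles the breakdown and reacts monotonically", {
  eq <- equipment_spec()
  ec <- econ_config()
  e <- cost_breakdown_at(base_inputs(), eq, ec, price = 20)
  items <- unlist(e$breakdown)
  expect_equal(sum(items), e$annual_cost_usd)
  expect_equal(e$annual_throughput_kg,
               e$n_batches * run_batch(base_inputs(), eq, ec)$final_product_kg)
  ## determinism
  e2 <- cost_breakdown_at(base_inputs(), eq, ec, price = 20)
  expect_identical(e[names(e) != "breakdown"], e2[names(e2) != "breakdown"])
  ## IRR satisfies its own NPV identity
  cfv <- c(-e$capex_usd, rep((20 * e$annual_throughput_kg * 1000 -
                                (e$annual_cost_usd - e$capex_usd / ec$depreciation_years)) -
                               ec$tax_rate * pmax(20 * e$annual_throughput_kg * 1000 -
                                                    e$annual_cost_usd, 0),
                             ec$project_years))
  expect_lt(abs(sum(cfv / (1 + e$irr_after_tax)^(0:ec$project_years))),
            1e-6 * e$capex_usd)
  ## higher expression (pre-clamp) raises IRR and lowers COGS; a modestly
  ## oversized column keeps the CEX cap out of the sweep range
  sweep <- seq(1.0, 1.9, by = 0.3)
  eq_wide <- equipment_spec(cex_column_diameter = 3)
  res <- lapply(sweep, function(v)
    run_tea(base_inputs(expression_level = v), eq_wide, ec, price = 20))
  irrs <- vapply(res, `[[`, numeric(1), "irr_after_tax")
  cogs <- vapply(res, `[[`, numeric(1), "cogs_usd_g")
  expect_true(all(diff(irrs) > 0))
  expect_true(all(diff(cogs) < 0))
  ## same monotonicity in each recovery
  for (nm in c("pf_recovery", "tff_recovery", "cex_recovery")) {
    vals <- seq(0.85, 0.97, by = 0.04)
    r2 <- vapply(vals, function(v) {
      args <- stats::setNames(list(v), nm)
      run_tea(do.call(base_inputs, args), eq_wide, ec, price = 20)$irr_after_tax
    }, numeric(1))
    expect_true(all(diff(r2) > 0))
  }
  ## COGS halves when annual product doubles at fixed cost
  expect_equal(e$annual_cost_usd / (2 * e$annual_throughput_kg * 1000),
               e$cogs_usd_g / 2)
})

test_that("mass conservation with slack holds across random trials", {
  x <- sample_trials(default_registry(), n = 500, seed = 55)
  b <- run_batch(x, equipment_spec(), econ_config())
  pk <- b$product_kg
  expect_true(all(pk[, "pf"] <= pk[, "crude"] + 1e-12))
  expect_true(all(pk[, "tff"] <= pk[, "pf"] + 1e-12))
  expect_true(all(pk[, "cex"] <= pk[, "tff"] + 1e-12))
  expect_true(all(b$purity > 0 & b$purity <= 1))
  ## equality through a stage iff recovery = 1 and no clamp
  lossless <- base_inputs(pf_recovery = 1)
  bl <- run_batch(lossless, equipment_spec(oversize_factor = 5), econ_config())
  expect_equal(unname(bl$product_kg[1, "pf"]), unname(bl$product_kg[1, "crude"]))
})

test_that("input validation names the offending stage", {
  eq <- equipment_spec(); ec <- econ_config()
  expect_error(run_batch(base_inputs(pf_recovery = 1.2), eq, ec),
               "pf_recovery")
  expect_error(run_batch(base_inputs(expression_level = -1), eq, ec),
               "expression")
  expect_error(run_batch(base_inputs()[, -1], eq, ec), "missing columns")
})
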