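test_that("the default registry carries the base-case assumption set", {
  reg <- default_registry()
  expect_length(reg, 9)
  expect_setequal(names(reg),
                  c("field_growth_yield", "field_growth_time",
                    "expression_level", "harvest_time", "pf_recovery",
                    "pf_flux", "tff_recovery", "tff_flux", "cex_recovery"))
  expect_equal(reg$field_growth_yield$family, "beta4")
  expect_equal(unlist(reg$field_growth_yield$params),
               c(alpha = 2.57, beta = 4.80, minimum = 0.63, maximum = 1))
  expect_equal(asm_mean(reg$expression_level), 1.50)
  ## CEX recovery support width is 20% of its base value
  pr <- reg$cex_recovery$params
  expect_equal(pr$maximum - pr$minimum, 0.2 * (pr$maximum + pr$minimum) / 2)
  ## UF/DF flux spans base +/- 25%
  fl <- reg$tff_flux$params
  expect_equal(fl$minimum / fl$mode, 0.75)
  expect_equal(fl$maximum / fl$mode, 1.25)
  ## harvest-time bounds follow from the 1-10 km/h speed range
  ht <- reg$harvest_time$params
  expect_equal(ht$minimum, 80 / 10)
  expect_equal(ht$maximum, 80 / 1)
})

test_that("normalize_to_mean hits the target under both policies", {
  lg <- assumption("x", "logistic", list(location = 2, scale = 0.3))
  out <- normalize_to_mean(lg, 1.5)
  expect_equal(out$params$location, 1.5)
  expect_equal(out$params$scale, 0.3)
  un <- assumption("y", "uniform", list(minimum = 0.9, maximum = 1.1))
  out2 <- normalize_to_mean(un, 2, method = "scale")
  expect_equal(unlist(out2$params), c(minimum = 1.8, maximum = 2.2))
  ## identity when already at target
  tri <- assumption("z", "triangular", list(minimum = 1, mode = 2, maximum = 3))
  expect_equal(normalize_to_mean(tri, 2)$params, tri$params)
  expect_equal(asm_mean(normalize_to_mean(tri, 5)), 5)
})

test_that("sampled marginals respect support, truncation, and means", {
  reg <- default_registry()
  x <- sample_trials(reg, n = 20000, seed = 101)
  expect_equal(dim(x), c(20000L, 9L))
  ## support per family
  expect_true(all(x$field_growth_yield >= 0.63 & x$field_growth_yield <= 1))
  expect_true(all(x$harvest_time >= 8 & x$harvest_time <= 80))
  expect_true(all(x$cex_recovery >= 0.81 & x$cex_recovery <= 0.99))
  tri <- reg$field_growth_time$params
  expect_true(all(x$field_growth_time >= tri$minimum &
                    x$field_growth_time <= tri$maximum))
  expect_true(all(x$expression_level > 0))    # truncated logistic
  ## marginal means within 3 standard errors of the analytic means
  for (nm in names(reg)) {
    m <- asm_mean(reg[[nm]])
    se <- sd(x[[nm]]) / sqrt(nrow(x))
    expect_lt(abs(mean(x[[nm]]) - m), 3 * se + 1e-3 * abs(m))
  }
  ## the 20,000-draw yield column mean sits at the base case 0.76
  expect_equal(mean(x$field_growth_yield), 0.759, tolerance = 0.01)
})

test_that("sampling is bit-reproducible and independent by default", {
  reg <- default_registry()
  a <- sample_trials(reg, n = 5000, seed = 7)
  b <- sample_trials(reg, n = 5000, seed = 7)
  expect_identical(a, b)
  x <- sample_trials(reg, n = 20000, seed = 13)
  rho <- stats::cor(as.matrix(x), method = "spearman")
  expect_lt(max(abs(rho[upper.tri(rho)])), 0.03)
})

test_that("rank-correlation induction hits the target without disturbing
           the marginals", {
  reg <- tiny_registry()
  corr <- correlation_spec("u1", "u2", 0.8)
  x <- sample_trials(reg, corr, n = 20000, seed = 3)
  rho <- stats::cor(x$u1, x$u2, method = "spearman")
  expect_lt(abs(rho - 0.8), 0.05)
  ## untargeted pair stays independent
  expect_lt(abs(stats::cor(x$u1, x$t1, method = "spearman")), 0.05)
  ## reordering leaves each marginal exactly intact
  x0 <- sample_trials(reg, NULL, n = 20000, seed = 3)
  expect_equal(sort(x$u1), sort(x0$u1))
  expect_equal(sort(x$t1), sort(x0$t1))
})

test_that("non-positive-definite correlation targets are rejected by name", {
  reg <- tiny_registry()
  corr <- correlation_spec(c("u1", "u1", "u2"), c("u2", "t1", "t1"),
                           c(0.9, 0.9, -0.9))
  expect_error(sample_trials(reg, corr, n = 100, seed = 1),
               "not positive definite.*u1")
})

test_that("marginal empirical CDFs pass a KS self-consistency check", {
  reg <- default_registry()
  x <- sample_trials(reg, n = 20000, seed = 5)
  for (nm in c("field_growth_yield", "expression_level", "pf_flux",
               "cex_recovery")) {
    u <- asm_cdf(reg[[nm]], x[[nm]])    # PIT: uniform under the null
    ks <- suppressWarnings(stats::ks.test(u, "punif"))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("triangular distribution functions agree with simulation", {
  p <- c(0.1, 0.5, 0.9)
  q <- qtri(p, 1, 2, 4)
  expect_equal(ptri(q, 1, 2, 4), p)
  expect_equal(qtri(c(0, 1), 1, 2, 4), c(1, 4))
  expect_equal(stats::integrate(dtri, 1, 4, minimum = 1, mode = 2,
                                maximum = 4)$value, 1, tolerance = 1e-6)
  set.seed(8)
  draws <- rtri(50000, 1, 2, 4)
  expect_equal(mean(draws), (1 + 2 + 4) / 3, tolerance = 0.01)
  expect_error(qtri(0.5, 3, 2, 1), "triangular")
})

test_that("registry JSON round-trips", {
  reg <- default_registry()
  f <- withr::local_tempfile(fileext = ".json")
  write_registry(reg, f)
  back <- read_registry(f)
  expect_equal(names(back), names(reg))
  for (nm in names(reg)) {
    expect_equal(back[[nm]]$family, reg[[nm]]$family)
    expect_equal(unlist(back[[nm]]$params), unlist(reg[[nm]]$params))
    expect_equal(back[[nm]]$truncation, reg[[nm]]$truncation)
  }
  x1 <- sample_trials(reg, n = 100, seed = 2)
  x2 <- sample_trials(back, n = 100, seed = 2)
  expect_equal(as.data.frame(x1), as.data.frame(x2))
})
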