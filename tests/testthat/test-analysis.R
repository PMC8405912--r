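test_that("scenario comparison matches brute-force t and KS statistics", {
  set.seed(41)
  for (i in 1:10) {
    n1 <- sample(5:100, 1); n2 <- sample(5:100, 1)
    a <- rnorm(n1); b <- rnorm(n2, 0.3)
    cmp <- compare_scenarios(a, b)
    ## Welch t by hand
    t_ref <- (mean(a) - mean(b)) / sqrt(var(a) / n1 + var(b) / n2)
    expect_equal(cmp$t_stat, t_ref, tolerance = 1e-12)
    ## KS D as the brute-force sup over the pooled points
    grid <- sort(c(a, b))
    d_ref <- max(abs(vapply(grid, function(g) mean(a <= g) - mean(b <= g),
                            numeric(1))))
    expect_equal(cmp$ks_d, d_ref, tolerance = 1e-12)
    expect_true(cmp$ks_d >= 0 && cmp$ks_d <= 1)
    expect_true(cmp$t_p >= 0 && cmp$t_p <= 1)
  }
})

test_that("comparison detects a unit mean shift and flags degenerate input", {
  set.seed(17)
  a <- rnorm(5000); b <- rnorm(5000, 1)
  cmp <- compare_scenarios(a, b, forecast = "irr_after_tax")
  expect_lt(cmp$t_p, 1e-10)
  expect_lt(cmp$ks_p, 1e-10)
  same <- compare_scenarios(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$ks_d, 0)
  expect_equal(same$t_stat, 0)
  deg <- compare_scenarios(rep(1, 5), rep(1, 5))
  expect_false(deg$t_defined)
  expect_true(is.na(deg$t_stat))
})

test_that("qq points are monotone with slope ~1 for normal samples", {
  set.seed(23)
  qq <- qq_points(rnorm(10000))
  expect_true(all(diff(qq$theoretical) >= 0))
  expect_true(all(diff(qq$sample) >= 0))
  slope <- coef(lm(sample ~ theoretical, qq))[2]
  expect_equal(unname(slope), 1, tolerance = 0.05)
  flat <- qq_points(rep(2, 10))
  expect_equal(unname(coef(lm(sample ~ theoretical, flat))[2]), 0)
  expect_error(qq_points(c(1, 2)), "three")
})

test_that("tornado sweeps quantiles and ranks by swing", {
  reg <- tiny_registry()
  base <- registry_base(reg)
  ident <- function(x) x$u1
  res <- tornado(ident, base, reg, percentiles = c(0.1, 0.9))
  expect_s3_class(res, "tornado_result")
  expect_equal(res$swing[res$parameter == "u1"], 0.8)
  ## inactive parameters swing zero and rank last
  expect_equal(res$swing[res$parameter %in% c("u2", "t1")], c(0, 0))
  expect_equal(res$parameter[1], "u1")
  ## linear additive model: swings proportional to coefficient x quantile range
  lin <- function(x) 2 * x$u1 + 1 * x$u2
  rl <- tornado(lin, base, reg, c(0.25, 0.75))
  expect_equal(rl$swing[rl$parameter == "u1"], 2 * 0.5)
  expect_equal(rl$swing[rl$parameter == "u2"], 1 * 0.5)
  expect_true(all(diff(rl$swing) <= 0))
  ## swing of one parameter is invariant to other parameters' distributions
  reg2 <- tiny_registry()
  reg2$u2 <- assumption("u2", "uniform", list(minimum = -5, maximum = 5))
  rl2 <- tornado(lin, registry_base(reg2), reg2, c(0.25, 0.75))
  expect_equal(rl2$swing[rl2$parameter == "u1"],
               rl$swing[rl$parameter == "u1"])
  expect_error(tornado(ident, base, reg, c(0.9, 0.1)), "lo < hi")
  ## model failure at an extreme is recorded, not fatal
  bad <- function(x) if (x$u1 > 0.85) stop("boom") else x$u1
  rb <- tornado(bad, base, reg, c(0.1, 0.9))
  expect_false(rb$ok[rb$parameter == "u1"])
})

test_that("spider curves pass through the base point and flatten for
           inactive parameters", {
  reg <- tiny_registry()
  base <- registry_base(reg)
  lin <- function(x) 3 * x$u1 + x$t1
  res <- spider(lin, base, reg, grid = c(0.25, 0.5, 0.75))
  expect_s3_class(res, "spider_result")
  ## u2 is inactive: flat line
  expect_equal(diff(range(res$value[res$parameter == "u2"])), 0)
  ## u1 curve is linear in the parameter value
  u1v <- asm_quantile(reg$u1, c(0.25, 0.5, 0.75))
  expect_equal(res$value[res$parameter == "u1"], 3 * u1v + base$t1)
  ## all curves meet at the base percentile of a symmetric uniform (p = 0.5)
  at_mid <- res$value[res$percentile == 0.5]
  expect_equal(at_mid[1], at_mid[2], tolerance = 1e-9)
})

test_that("contribution to variance follows the signed squared-Spearman
           convention", {
  set.seed(71)
  n <- 20000
  x1 <- runif(n); x2 <- runif(n)
  ## single driver takes 100%
  one <- contribution_to_variance(data.frame(x1 = x1), x1)
  expect_equal(one$share_pct, 100)
  ## equal-variance additive inputs split 50/50 within 3%
  ctv <- contribution_to_variance(data.frame(x1 = x1, x2 = x2), x1 + x2)
  expect_equal(sum(abs(ctv$share_pct)), 100, tolerance = 0.1)
  expect_lt(max(abs(ctv$share_pct - 50)), 3)
  ## unequal coefficients order the shares
  ctv2 <- contribution_to_variance(data.frame(x1 = x1, x2 = x2), 2 * x1 + x2)
  s <- setNames(ctv2$share_pct, ctv2$parameter)
  expect_gt(s["x1"], s["x2"])
  ## negative dependence carries a negative sign
  ctv3 <- contribution_to_variance(data.frame(x1 = x1, x2 = x2), -x1 + x2)
  s3 <- setNames(ctv3$share_pct, ctv3$parameter)
  expect_lt(s3["x1"], 0)
  expect_equal(sum(abs(ctv3$share_pct)), 100, tolerance = 0.1)
  ## matches a brute-force computation
  rho_ref <- c(cor(rank(x1), rank(2 * x1 + x2)),
               cor(rank(x2), rank(2 * x1 + x2)))
  share_ref <- sign(rho_ref) * rho_ref^2 / sum(rho_ref^2) * 100
  expect_equal(sort(ctv2$share_pct), sort(share_ref), tolerance = 1e-9)
  expect_error(contribution_to_variance(data.frame(x = 1:10), 1:10),
               "at least 30")
})

test_that("extremal trials follow the min / nearest-mean / max rule with
           first-index ties", {
  rec <- data.frame(trial = 1:3, irr = c(1, 2, 3))
  ex <- extremal_trials(rec, "irr")
  expect_equal(ex$minimum$trial, 1)
  expect_equal(ex$nearest_mean$trial, 2)
  expect_equal(ex$maximum$trial, 3)
  rec2 <- data.frame(trial = 1:4, irr = c(1, 1, 2.4, 3))
  expect_equal(extremal_trials(rec2, "irr")$minimum$trial, 1)  # tie: first
  ## sample mean 2.4: the trial with value 2 is nearest
  rec3 <- data.frame(trial = 1:4, irr = c(1, 2, 3, 3.6))
  expect_equal(extremal_trials(rec3, "irr")$nearest_mean$irr, 2)
  expect_error(extremal_trials(rec, "nope"), "unknown forecast")
})
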