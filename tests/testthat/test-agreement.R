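test_that("Pearson correlation handles exact linear relations and errors", {
  x <- c(0.3, 1.2, 2.5, 3.1, 4.8)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  set.seed(2)
  a <- rnorm(10); b <- rnorm(10)
  oracle <- mean((a - mean(a)) * (b - mean(b))) / (sd(a) * sd(b)) * 10 / 9
  expect_equal(pearson_r(a, b), oracle, tolerance = 1e-12)
  expect_error(pearson_r(rep(1, 5), 1:5), "constant")
  expect_error(pearson_r(1:2, 1:2), "n >= 3")
})

test_that("paired t follows the difference formula", {
  x <- c(1, 2, 3, 4)
  r <- paired_t(x, x)
  expect_equal(r$t, 0); expect_equal(r$p, 1); expect_equal(r$df, 3)
  # zero-mean alternating differences
  expect_equal(paired_t(c(1, 0, 1, 0), c(0, 1, 0, 1))$t, 0)
  # 8-pair instance against the explicit formula
  a <- c(12.1, 11.4, 13.2, 10.9, 12.8, 11.1, 12.4, 13.0)
  b <- c(11.8, 11.9, 12.5, 10.2, 13.1, 10.4, 12.0, 12.5)
  d <- a - b
  t_or <- mean(d) / (sd(d) / sqrt(8))
  r <- paired_t(a, b)
  expect_equal(r$t, t_or, tolerance = 1e-10)
  expect_equal(r$p, 2 * pt(-abs(t_or), 7), tolerance = 1e-10)
  # agrees with stats::t.test
  tt <- t.test(a, b, paired = TRUE)
  expect_equal(r$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(r$p, tt$p.value, tolerance = 1e-12)
  # antisymmetry in t, invariant p
  r2 <- paired_t(b, a)
  expect_equal(r2$t, -r$t)
  expect_equal(r2$p, r$p)
  # constant nonzero differences: infinite t, p = 0
  r3 <- paired_t(c(2, 3, 4), c(1, 2, 3))
  expect_equal(r3$t, Inf); expect_equal(r3$p, 0)
})

test_that("Lin's CCC uses n-denominator moments and is bounded by |r|", {
  x <- c(0.5, 1.1, 2.3, 3.7, 4.2)
  expect_equal(lins_ccc(x, x), 1)
  expect_equal(lins_ccc(c(-1, 0, 1), c(1, 0, -1)), -1)
  # hand computation: 2*1.25 / (1.25 + 1.25 + 1)
  expect_equal(lins_ccc(c(1, 2, 3, 4), c(2, 3, 4, 5)), 2 * 1.25 / 3.5,
               tolerance = 1e-12)
  set.seed(4)
  for (i in 1:20) {
    a <- rnorm(15); b <- rnorm(15, 1, 2)
    expect_lte(abs(lins_ccc(a, b)), abs(pearson_r(a, b)) + 1e-12)
  }
  # equality when means and variances match exactly
  a <- c(1, 2, 3); b <- c(3, 2, 1)
  expect_equal(abs(lins_ccc(a, b)), abs(pearson_r(a, b)))
})

test_that("Bland-Altman bias, limits and outside counts are correct", {
  x <- c(0.6, 0.7, 0.8, 0.65)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$bias, 0); expect_equal(ba0$sd_diff, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))
  expect_equal(ba0$n_outside, 0)
  # constant offset
  ba1 <- bland_altman(x, x - 0.05)
  expect_equal(ba1$bias, 0.05); expect_equal(ba1$sd_diff, 0)
  # limits widen and the outside fraction shrinks as k grows
  set.seed(6)
  m <- rnorm(500); p <- m + rnorm(500, 0, 0.2)
  ks <- c(1, 1.96, 2.5)
  bas <- lapply(ks, function(k) bland_altman(m, p, k))
  w <- vapply(bas, function(b) b$loa_high - b$loa_low, numeric(1))
  expect_true(all(diff(w) > 0))
  out <- vapply(bas, `[[`, numeric(1), "pct_outside")
  expect_true(all(diff(out) <= 0))
})

test_that("bias percentage is the mean difference over the mean measured", {
  v <- c(0.7, 0.72, 0.68)
  expect_equal(bias_percent(v, v), 0)
  expect_equal(bias_percent(rep(1, 4), rep(0.99, 4)), 1, tolerance = 1e-12)
  m <- c(1.2, 0.8, 1.1, 0.9, 1.0); p <- c(1.1, 0.9, 1.0, 1.0, 0.9)
  expect_equal(bias_percent(m, p), mean(m - p) / mean(m) * 100)
  expect_error(bias_percent(c(-1, 1), c(0, 0)), "zero")
})

test_that("repeated-measures ANOVA matches aov error-strata decomposition", {
  # identical conditions: F = 0, p = 1
  m0 <- matrix(rep(c(1.5, 1.6, 1.4), 3), nrow = 3)
  r0 <- rm_anova_oneway(m0)
  expect_equal(r0$F, 0); expect_equal(r0$p, 1)
  # small instance against the explicit decomposition and against aov
  m <- matrix(c(1.2, 1.5, 1.1, 1.4, 1.8, 1.3), nrow = 3)
  r <- rm_anova_oneway(m)
  expect_equal(r$df1, 1); expect_equal(r$df2, 2)
  long <- data.frame(y = as.vector(m),
                     subj = factor(rep(1:3, 2)),
                     cond = factor(rep(1:2, each = 3)))
  av <- summary(aov(y ~ cond + Error(subj), data = long))
  tab <- av[["Error: Within"]][[1]]
  expect_equal(r$F, tab[1, "F value"], tolerance = 1e-10)
  expect_equal(r$p, tab[1, "Pr(>F)"], tolerance = 1e-10)
  # larger random instance
  set.seed(8)
  m2 <- matrix(rnorm(36), nrow = 12)
  r2 <- rm_anova_oneway(m2)
  long2 <- data.frame(y = as.vector(m2), subj = factor(rep(1:12, 3)),
                      cond = factor(rep(1:3, each = 12)))
  tab2 <- summary(aov(y ~ cond + Error(subj), data = long2))[[
    "Error: Within"]][[1]]
  expect_equal(r2$F, tab2[1, "F value"], tolerance = 1e-10)
  # invariant to adding per-subject constants
  r3 <- rm_anova_oneway(m2 + rnorm(12) %o% rep(1, 3))
  expect_equal(r3$F, r2$F, tolerance = 1e-8)
  expect_error(rm_anova_oneway(matrix(c(1, NA, 2, 3), 2)), "missing")
})

test_that("post-hoc pairwise tests apply the Bonferroni rule", {
  m <- cbind(a = c(1.2, 1.5, 1.1, 1.6), b = c(1.3, 1.4, 1.2, 1.8),
             c = c(1.6, 1.9, 1.5, 2.0))
  out <- post_hoc_pairwise(m)
  expect_equal(nrow(out), 3)
  for (i in 1:3) {
    raw <- paired_t(m[, out$cond_a[i]], m[, out$cond_b[i]])
    expect_equal(out$t[i], raw$t, tolerance = 1e-12)
    expect_equal(out$p_adj[i], min(1, 3 * raw$p), tolerance = 1e-12)
  }
  out_same <- post_hoc_pairwise(cbind(a = m[, 1], b = m[, 1]))
  expect_equal(out_same$p, 1)
})

test_that("the agreement report aggregates all statistics coherently", {
  set.seed(10)
  meas <- rnorm(120, 0.68, 0.11)
  pred <- meas + rnorm(120, 0.002, 0.07)
  rep <- agreement_report(meas, pred)
  expect_equal(rep$n, 120)
  expect_equal(rep$ccc, lins_ccc(meas, pred))
  expect_equal(rep$bias_percent, bias_percent(meas, pred))
  expect_lte(abs(rep$ccc), abs(rep$pearson_r))
  ba <- rep$bland_altman
  expect_lte(ba$loa_low, ba$bias); expect_lte(ba$bias, ba$loa_high)
  expect_equal(rep$paired_t$df, 119)
})
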