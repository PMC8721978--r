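test_that("development/validation split follows the floor rule", {
  rec <- data.frame(grf_v_l_bw = rnorm(1579), c7acc = rnorm(1579),
                    subject_id = rep(sprintf("S%02d", 1:12), length.out = 1579))
  sp <- split_dd_vd(rec, ratio = 2 / 3, seed = 1)
  expect_equal(nrow(sp$dd), floor(2 * 1579 / 3))  # 1052
  expect_equal(nrow(sp$vd), 1579 - 1052)
  # disjoint, exhaustive, deterministic
  expect_length(intersect(rownames(sp$dd), rownames(sp$vd)), 0)
  expect_setequal(c(rownames(sp$dd), rownames(sp$vd)), rownames(rec))
  sp2 <- split_dd_vd(rec, ratio = 2 / 3, seed = 1)
  expect_identical(sp$dd, sp2$dd)
  expect_error(split_dd_vd(rec, ratio = 1.2), "ratio")
  expect_error(split_dd_vd(rec[1:5, ], 2 / 3), "at least 10")
})

test_that("stratified split applies the floor rule within each stratum", {
  rec <- data.frame(x = rnorm(60), subject_id = rep(c("A", "B", "C"), 20))
  sp <- split_dd_vd(rec, ratio = 2 / 3, seed = 2, stratify_by = "subject_id")
  expect_equal(unname(table(sp$dd$subject_id)), rep(13L, 3),
               ignore_attr = TRUE)
  expect_error(split_dd_vd(rec, seed = 1, stratify_by = "nope"), "not found")
})

test_that("OLS fit matches the normal-equations oracle", {
  # exact linear data
  x <- 1:20
  m <- suppressWarnings(fit_linear_model(2 + 3 * x, data.frame(x = x)))
  expect_equal(unname(coef(m)), c(2, 3), tolerance = 1e-10)
  expect_equal(m$adjusted_r2, 1, tolerance = 1e-10)
  # 20 x 3 instance against explicit (X'X)^-1 X'y
  set.seed(5)
  X <- data.frame(a = rnorm(20), b = rnorm(20), c = rnorm(20))
  y <- 1 + 0.5 * X$a - 2 * X$b + rnorm(20)
  m <- fit_linear_model(y, X)
  M <- cbind(1, as.matrix(X))
  beta <- solve(t(M) %*% M, t(M) %*% y)
  expect_equal(unname(coef(m)), unname(beta[, 1]), tolerance = 1e-8)
  # adjusted R2 identity and bound
  p <- 3; n <- 20
  expect_equal(m$adjusted_r2, 1 - (1 - m$r2) * (n - 1) / (n - p - 1))
  expect_lte(m$adjusted_r2, m$r2)
})

test_that("degenerate designs are rejected with informative errors", {
  expect_error(fit_linear_model(rnorm(3), data.frame(a = rnorm(3),
                                                     b = rnorm(3),
                                                     c = rnorm(3))),
               "more observations")
  expect_error(fit_linear_model(rnorm(10), data.frame(a = rep(1, 10))),
               "constant")
  set.seed(1)
  a <- rnorm(20)
  expect_error(fit_linear_model(rnorm(20), data.frame(a = a, b = 2 * a)),
               "collinear.*b")
})

test_that("backward elimination keeps strong terms and drops noise", {
  tr <- toy_regression(500, sd = 0.5, seed = 11)
  m <- backward_eliminate(tr$y, tr$X)
  expect_setequal(m$terms, c("x1", "x2"))  # both strongly significant
  # an appended pure-noise column is removed (p ~ U(0,1) > 0.1 here)
  set.seed(12)
  X2 <- cbind(tr$X, z = rnorm(500))
  m2 <- backward_eliminate(tr$y, X2)
  expect_setequal(m2$terms, c("x1", "x2"))
  expect_equal(m2$trail$removed, "z")
})

test_that("exact p-value ties remove the later-named column", {
  # x1, x2 orthogonal to y and to each other: both t = 0, an exact tie
  x1 <- c(1, -1, 0, 0, 0, 0)
  x2 <- c(0, 0, 1, -1, 0, 0)
  y <- c(0, 0, 0, 0, 1, -1)
  expect_warning(m <- backward_eliminate(y, data.frame(a = x1, b = x2)),
                 "intercept-only")
  expect_equal(m$trail$removed[1], "b")
  expect_length(m$terms, 0)
})

test_that("the final model is invariant to predictor column order", {
  set.seed(13)
  for (i in 1:5) {
    n <- 200
    X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n), d = rnorm(n))
    y <- 0.5 + 1.2 * X$a - 0.8 * X$b + rnorm(n)
    m1 <- suppressWarnings(backward_eliminate(y, X))
    m2 <- suppressWarnings(backward_eliminate(y, X[, c("d", "b", "c", "a")]))
    expect_setequal(m1$terms, m2$terms)
  }
})

test_that("noiseless reference-equation data are recovered exactly", {
  rec <- simulate_records(12, seed = 20, grf_from = "reference",
                          sigma_ref = 0)
  m <- backward_eliminate(rec$grf_v_l_bw,
                          rec[, c("c7acc", "pwdh", "age", "weight")])
  expect_setequal(m$terms, c("c7acc", "pwdh", "age", "weight"))
  ref <- coef(grf_reference_model())
  expect_equal(coef(m)[names(ref)], ref, tolerance = 1e-8)
})

test_that("the reference equation predicts the published worked example", {
  # validation-set mean inputs
  expect_equal(predict_grf(1.568, 100 / 158.2 * 100, 23.6, 53.1),
               0.679, tolerance = 0.02 / 0.679)
  # hand-arithmetic oracle
  expect_equal(predict_grf(1.5, 60, 25, 55), 0.600, tolerance = 1e-10)
  # an intercept-only model predicts its intercept
  m0 <- aquagrf:::new_grf_model(c(`(Intercept)` = 0.7), NULL, NA, NA, NA)
  expect_equal(predict(m0, data.frame(x = 1:3)), rep(0.7, 3))
  expect_error(predict_grf(Inf, 60, 25, 55), "finite")
})

test_that("fraction-scale PWDH triggers a unit-sanity warning", {
  expect_warning(predict_grf(1.5, 0.632, 25, 55), "percent")
})

test_that("fit_grf_model wires records into backward elimination", {
  rec <- simulate_records(6, seed = 30, grf_from = "reference",
                          sigma_ref = 0.07)
  m <- fit_grf_model(rec)
  expect_s3_class(m, "grf_model")
  expect_true("c7acc" %in% m$terms)
  expect_gt(m$adjusted_r2, 0.3)
  expect_error(fit_grf_model(rec[, 1:3]), "missing column")
  # residuals/predict methods work on the fit
  expect_length(residuals(m), nrow(rec))
  expect_equal(length(predict(m, rec)), nrow(rec))
})

test_that("group comparison matches the pooled-variance oracle", {
  dd <- data.frame(v = c(1, 2, 3, 4, 5))
  vd <- data.frame(v = c(2, 4, 6))
  out <- compare_groups(dd, vd, "v")
  n1 <- 5; n2 <- 3
  sp2 <- ((n1 - 1) * var(dd$v) + (n2 - 1) * var(vd$v)) / (n1 + n2 - 2)
  t_oracle <- (mean(dd$v) - mean(vd$v)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  expect_equal(out$t, t_oracle, tolerance = 1e-10)
  expect_equal(out$p, 2 * pt(-abs(t_oracle), n1 + n2 - 2), tolerance = 1e-10)
  # identical groups: t = 0, p = 1
  out0 <- compare_groups(dd, dd, "v")
  expect_equal(out0$t, 0)
  expect_equal(out0$p, 1)
  expect_error(compare_groups(dd[1, , drop = FALSE], vd, "v"), "at least 2")
})

test_that("split p-values are uniform under the null across seeds", {
  rec <- data.frame(grf_v_l_bw = rnorm(240), c7acc = rnorm(240))
  pvals <- vapply(1:200, function(seed) {
    sp <- split_dd_vd(rec, 2 / 3, seed = seed)
    compare_groups(sp$dd, sp$vd, "grf_v_l_bw")$p
  }, numeric(1))
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})
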