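test_that("treatment transforms follow their definitions", {
  ex <- toy_exposures(5, coal = c(6L, 0L, 1L, 2L, 4L))
  expect_equal(transform_treatment(ex, "topcoded"), c(4, 0, 1, 2, 4))
  expect_equal(transform_treatment(ex, "binary"), c(1, 0, 1, 1, 1))
  expect_equal(transform_treatment(ex, "count"), c(6, 0, 1, 2, 4))
  w <- c(10, 20, 5, 5, 10)
  dm <- transform_treatment(ex, "demeaned_count", weights = w)
  expect_equal(sum(w * dm), 0)
  expect_error(transform_treatment(ex, "log"), class = "coalcough_usage_error")
})

test_that("within transform demeans exactly and zeroes degenerate groups", {
  df <- data.frame(household_id = c(1, 1), psu_id = 1, v = c(3, 5))
  expect_equal(as.vector(within_transform(df, "household", "v")), c(-1, 1))
  # constant within group -> all zeros; singleton group -> zero row
  df2 <- data.frame(household_id = c(1, 1, 2), psu_id = 1, v = c(4, 4, 9))
  expect_equal(as.vector(within_transform(df2, "household", "v")), c(0, 0, 0))
  # group means of demeaned data are zero to 1e-10
  set.seed(1)
  df3 <- data.frame(household_id = rep(1:50, each = 2), psu_id = 1,
                    v = rnorm(100))
  d <- within_transform(df3, "household", "v")
  expect_lt(max(abs(tapply(d[, 1], df3$household_id, mean))), 1e-10)
  df3$v[4] <- NA
  expect_error(within_transform(df3, "household", "v"),
               class = "coalcough_missing_data")
})

test_that("FE-OLS equals dummy-variable OLS on a small fixture", {
  set.seed(42)
  n_hh <- 6
  dist <- c(1, 1, 2, 2, 3, 3)
  psu <- c(1, 1, 2, 2, 3, 3)
  p <- toy_panel(n_hh, dist, psu, function(hh, wave) 0)
  p$cough <- round(runif(12), 3)
  p$ln_cons_pc <- rnorm(12, 9.6, 0.5)
  ex <- toy_exposures(3, coal = c(2L, 0L, 1L))
  fit <- fit_lpm(p, ex, regression_spec(controls = "demographic"))

  treat <- ex$coal_plants_gained[match(p$district_id, ex$district_id)] * p$wave
  ref <- lm(cough ~ treat + wave + ln_cons_pc + hh_size +
              factor(household_id), data = p)
  expect_equal(unname(fit$coefficients["coal_count"]),
               unname(coef(ref)["treat"]), tolerance = 1e-8)
  expect_equal(unname(fit$coefficients["round_2012"]),
               unname(coef(ref)["wave"]), tolerance = 1e-8)
  # hh_size is constant in the fixture -> dropped as collinear
  expect_true("hh_size" %in% fit$dropped_collinear)
})

test_that("two-district means-only toy recovers the hand-computed DiD", {
  # treated district changes by 0.03, control by 0.01, one plant gained:
  # beta = 0.02, round effect = 0.01
  n_hh <- 20
  dist <- rep(c(1, 2), each = 10)
  psu <- rep(1:4, each = 5)
  p <- toy_panel(n_hh, dist, psu, function(hh, wave) {
    if (wave == 0) 0 else if (dist[hh] == 1) 0.03 else 0.01
  })
  ex <- toy_exposures(2, coal = c(1L, 0L))
  fit <- fit_lpm(p, ex, regression_spec(controls = "none"))
  expect_equal(unname(fit$coefficients["coal_count"]), 0.02, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients["round_2012"]), 0.01, tolerance = 1e-10)
})

test_that("regressing the treatment on itself gives beta 1 and zero residuals", {
  dist <- rep(1:4, each = 3)
  psu <- rep(1:4, each = 3)
  p <- toy_panel(12, dist, psu, function(hh, wave) 0)
  ex <- toy_exposures(4, coal = c(3L, 1L, 0L, 2L))
  p$cough <- ex$coal_plants_gained[match(p$district_id, ex$district_id)] * p$wave
  fit <- fit_lpm(p, ex, regression_spec(controls = "none"))
  expect_equal(unname(fit$coefficients["coal_count"]), 1, tolerance = 1e-10)
  expect_lt(max(abs(fit$residuals)), 1e-10)
})

test_that("degenerate designs raise informative errors", {
  dist <- rep(1:2, each = 4)
  p <- toy_panel(8, dist, dist, function(hh, wave) runif(1))
  # all districts identically treated: treatment collinear with round FE
  ex <- toy_exposures(2, coal = c(1L, 1L))
  expect_error(fit_lpm(p, ex, regression_spec(controls = "none")),
               class = "coalcough_degenerate_design")
  # single cluster
  p2 <- toy_panel(8, rep(1:2, each = 4), rep(1L, 8), function(hh, wave) runif(1))
  ex2 <- toy_exposures(2, coal = c(1L, 0L))
  expect_error(fit_lpm(p2, ex2, regression_spec(controls = "none")),
               class = "coalcough_inference_error")
})

test_that("cluster-robust vcov matches a brute-force sandwich oracle", {
  set.seed(3)
  x <- cbind(a = rnorm(6), b = runif(6))
  e <- rnorm(6)
  cl <- c(1, 1, 1, 2, 2, 2)
  v <- cluster_robust_vcov(x, e, cl, df_correction = FALSE)
  # direct summation oracle
  bread <- solve(t(x) %*% x)
  meat <- matrix(0, 2, 2)
  for (g in unique(cl)) {
    xg <- x[cl == g, , drop = FALSE]; eg <- e[cl == g]
    sg <- t(xg) %*% eg
    meat <- meat + sg %*% t(sg)
  }
  oracle <- bread %*% meat %*% bread
  expect_lt(max(abs(v - oracle)), 1e-10)
  # CR1 factor
  v1 <- cluster_robust_vcov(x, e, cl, df_correction = TRUE)
  expect_equal(v1, v * (2 / 1) * (5 / 4), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("singleton clusters reduce the sandwich to the HC estimator", {
  set.seed(4)
  x <- cbind(1, rnorm(20))
  e <- rnorm(20)
  v <- cluster_robust_vcov(x, e, seq_len(20), df_correction = FALSE)
  bread <- solve(t(x) %*% x)
  hc0 <- bread %*% (t(x * e^2) %*% x) %*% bread
  expect_lt(max(abs(v - hc0)), 1e-12)
})

test_that("cluster-robust vcov is invariant to relabeling and row order", {
  set.seed(5)
  x <- cbind(a = rnorm(12), b = rnorm(12))
  e <- rnorm(12)
  cl <- rep(c("u", "v", "w"), each = 4)
  v1 <- cluster_robust_vcov(x, e, cl)
  v2 <- cluster_robust_vcov(x, e, rep(c(30, 2, 17), each = 4))
  ord <- sample(12)
  v3 <- cluster_robust_vcov(x[ord, ], e[ord], cl[ord])
  expect_equal(v1, v2, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(v1, v3, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("cluster-robust SEs agree with the sandwich package on real fits", {
  skip_if_not_installed("sandwich")
  tabs <- generate_panel(small_config(seed = 6))
  p <- tabs$panel; ex <- tabs$exposures
  fit <- fit_lpm(p, ex, regression_spec(controls = "none", fe_level = "psu",
                                        cluster_level = "psu"))
  treat <- ex$coal_plants_gained[match(p$district_id, ex$district_id)] * p$wave
  ref <- lm(cough ~ 0 + treat + wave + factor(psu_id), data = p)
  vr <- sandwich::vcovCL(ref, cluster = p$psu_id, type = "HC1",
                         cadjust = TRUE)
  expect_equal(unname(fit$coefficients["coal_count"]),
               unname(coef(ref)["treat"]), tolerance = 1e-8)
  # sandwich counts the explicit FE dummies in K; rescale to the package's
  # nested-cluster convention (absorbed intercepts excluded from K)
  n <- nrow(p); k_dummy <- length(coef(ref)); k_slope <- 2
  rescale <- sqrt((n - k_dummy) / (n - k_slope))
  expect_equal(unname(fit$se["coal_count"]),
               unname(sqrt(diag(vr))["treat"]) * rescale, tolerance = 1e-6)
})

test_that("clustered SEs approach classical SEs under independent errors", {
  set.seed(8)
  n <- 5000
  x <- cbind(a = rnorm(n))
  e <- rnorm(n)
  y <- x[, 1] * 0.5 + e
  b <- qr.coef(qr(x), y)
  r <- y - x %*% b
  v_cl <- cluster_robust_vcov(x, as.vector(r), sample(1:500, n, TRUE))
  v_classical <- sum(r^2) / (n - 1) * solve(t(x) %*% x)
  expect_lt(abs(sqrt(v_cl[1, 1]) / sqrt(v_classical[1, 1]) - 1), 0.1)
})

test_that("control blocks leave the coal coefficient essentially unchanged", {
  ests <- t(vapply(1:30, function(s) {
    tabs <- generate_panel(small_config(seed = s, households_per_psu = 20))
    f0 <- fit_lpm(tabs$panel, tabs$exposures, regression_spec(controls = "none"))
    f1 <- fit_lpm(tabs$panel, tabs$exposures, regression_spec(controls = "full"))
    c(unname(f0$coefficients["coal_count"]), unname(f1$coefficients["coal_count"]))
  }, numeric(2)))
  d <- ests[, 2] - ests[, 1]
  expect_lt(abs(mean(d)), 2 * sd(d) / sqrt(length(d)) + 1e-4)
})

test_that("treatment x urban interaction requires demeaning and estimates cleanly", {
  expect_error(regression_spec(extra_terms = "treatment_x_urban"),
               class = "coalcough_usage_error")
  tabs <- generate_panel(small_config(seed = 10))
  fit <- fit_lpm(tabs$panel, tabs$exposures,
                 regression_spec(treatment_transform = "demeaned_count",
                                 fe_level = "psu",
                                 extra_terms = c("urban_x_round",
                                                 "treatment_x_urban")))
  expect_true(all(c("coal_demeaned_count", "treatment_x_urban") %in%
                    names(fit$coefficients)))
  expect_true(all(fit$se[names(fit$coefficients)] > 0))
})
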