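test_that("balance test returns zero t for identical groups and matches the hand formula", {
  w0 <- data.frame(household_id = 1:8, psu_id = rep(1:4, each = 2),
                   district_id = rep(1:2, each = 4),
                   v = rep(c(0.2, 0.4), 4))
  treated <- w0$district_id == 2
  bal <- balance_test(w0, treated, "v")
  expect_equal(bal$t_stat, 0)

  # two clusters per group, hand-computed clustered SE of each mean:
  # Var(mean) = sum_g (sum of within-cluster deviations)^2 / n^2
  w1 <- data.frame(household_id = 1:8, psu_id = rep(1:4, each = 2),
                   district_id = rep(1:2, each = 4),
                   v = c(1, 2, 3, 6, 2, 2, 5, 9))
  treated1 <- w1$district_id == 2
  bal1 <- balance_test(w1, treated1, "v")
  g0 <- w1$v[1:4]; g1 <- w1$v[5:8]
  se0 <- sqrt(sum(tapply(g0 - mean(g0), rep(1:2, each = 2), sum)^2)) / 4
  se1 <- sqrt(sum(tapply(g1 - mean(g1), rep(1:2, each = 2), sum)^2)) / 4
  expect_equal(bal1$se_group0, se0)
  expect_equal(bal1$se_group1, se1)
  expect_equal(bal1$t_stat,
               (mean(g1) - mean(g0)) / sqrt(se0^2 + se1^2))
  expect_error(balance_test(w0, rep(TRUE, 8), "v"),
               class = "coalcough_degenerate_design")
})

test_that("baseline balance holds by construction on synthetic data", {
  # pooled over variables and seeds, |t| < 2 should hold about 95% of the
  # time (somewhat less with only ~24 treated-group clusters)
  tstats <- vapply(1:40, function(s) {
    tabs <- generate_panel(small_config(seed = 300 + s,
                                        households_per_psu = 15))
    w0 <- tabs$panel[tabs$panel$wave == 0, ]
    treated <- tabs$exposures$coal_plants_gained[
      match(w0$district_id, tabs$exposures$district_id)] > 0
    bal <- balance_test(w0, treated, c("cough", "fever", "diarrhea"))
    bal$t_stat
  }, numeric(3))
  expect_gte(mean(abs(tstats) < 2), 0.85)
})

test_that("pretrend regression identities hold", {
  cc <- data.frame(district_id = 1:10,
                   coal_plants_gained = c(0, 0, 0, 0, 0, 0, 1, 1, 2, 3),
                   d_imr = rnorm(10), d_female_literacy = rnorm(10),
                   d_total_literacy = rnorm(10), d_sanitation = rnorm(10),
                   d_electricity = rnorm(10))
  # outcome identically the regressor: slope 1, intercept 0
  cc$d_imr <- cc$coal_plants_gained
  f <- pretrend_regression(cc, "d_imr")
  expect_equal(unname(f$coefficients["coal"]), 1, tolerance = 1e-10)
  expect_equal(unname(f$coefficients["constant"]), 0, tolerance = 1e-10)
  # binary variant: intercept equals the untreated-district mean exactly
  set.seed(2)
  cc$d_sanitation <- rnorm(10, 13, 4)
  fb <- pretrend_regression(cc, "d_sanitation", treatment = "binary")
  expect_equal(unname(fb$coefficients["constant"]),
               mean(cc$d_sanitation[cc$coal_plants_gained == 0]),
               tolerance = 1e-10)
  # constant regressor errors
  cc0 <- cc; cc0$coal_plants_gained <- 0
  expect_error(pretrend_regression(cc0, "d_imr"),
               class = "coalcough_degenerate_design")
})

test_that("first principal component matches an eigendecomposition oracle", {
  set.seed(7)
  x <- matrix(rnorm(30), 6, 5,
              dimnames = list(NULL, c("d_imr", "d_female_literacy",
                                      "d_total_literacy", "d_sanitation",
                                      "d_electricity")))
  pc <- first_principal_component(x)
  ref <- prcomp(x, center = TRUE, scale. = TRUE)
  lead <- ref$rotation[, 1]
  if (lead["d_total_literacy"] < 0) lead <- -lead
  expect_equal(unname(pc$loadings), unname(lead), tolerance = 1e-8)
  expect_equal(pc$scores, unname(ref$x[, 1]) * sign(ref$rotation["d_total_literacy", 1]),
               tolerance = 1e-8)
  expect_equal(mean(pc$scores), 0, tolerance = 1e-12)
  # variance of scores equals the lead eigenvalue
  expect_equal(var(pc$scores), pc$eigenvalue, tolerance = 1e-10)

  # identical columns: scores proportional to the (standardized) column
  xi <- matrix(rep(rnorm(6), 5), 6, 5)
  pci <- first_principal_component(xi)
  expect_equal(abs(cor(pci$scores, xi[, 1])), 1, tolerance = 1e-10)
  expect_equal(unname(pci$loadings), rep(pci$loadings[[1]], 5),
               tolerance = 1e-10)

  xz <- x; xz[, 2] <- 3
  expect_error(first_principal_component(xz),
               class = "coalcough_standardization_error")
})

test_that("falsification suite labels results and finds injected effects", {
  tabs <- generate_panel(small_config(seed = 40))
  res <- falsification_suite(tabs$panel, tabs$exposures)
  expect_named(res, c("fever", "diarrhea", "noncoal_placebo"))
  expect_true("noncoal_count" %in%
                names(res$noncoal_placebo$coefficients))
  expect_equal(falsification_suite(tabs$panel, tabs$exposures,
                                   outcomes = character(),
                                   include_noncoal = FALSE), list())
  # power: an injected fever effect is detected at a generous size
  tabs2 <- generate_panel(synth_config(n_districts = 100,
                                       n_treated_districts = 14,
                                       psus_per_district = 4,
                                       households_per_psu = 25,
                                       beta_fever = 0.08, seed = 41))
  res2 <- falsification_suite(tabs2$panel, tabs2$exposures,
                              outcomes = "fever", include_noncoal = FALSE)
  f <- res2$fever
  expect_gt(f$coefficients["coal_count"] / f$se["coal_count"], 2)
})

test_that("migration exclusion drops whole households per rule", {
  tabs <- generate_panel(synth_config(n_districts = 80,
                                      n_treated_districts = 10,
                                      psus_per_district = 4,
                                      households_per_psu = 25,
                                      migration_fraction = 0.02,
                                      seed = 42))
  p <- tabs$panel
  expect_identical(migration_exclusion(p, "all"), p)
  f1 <- migration_exclusion(p, "drop_known_movers")
  f2 <- migration_exclusion(p, "drop_movers_and_unknown")
  # households removed in both waves or neither
  for (f in list(f1, f2))
    expect_true(all(table(f$household_id) == 2))
  n_hh <- length(unique(p$household_id))
  kept_frac <- length(unique(f1$household_id)) / n_hh
  expect_lt(abs(kept_frac - 0.98), 0.01)
  expect_lte(nrow(f2), nrow(f1))
  # strict rule removes exactly the missing-status households on top
  unknown <- unique(p$household_id[is.na(p$moved_within_7y)])
  mover <- unique(p$household_id[!is.na(p$moved_within_7y) &
                                   p$moved_within_7y == 1])
  expect_equal(length(unique(f1$household_id)) -
                 length(unique(f2$household_id)),
               length(setdiff(unknown, mover)))
})

test_that("coal estimate is stable under migration exclusion", {
  diffs <- vapply(1:20, function(s) {
    tabs <- generate_panel(small_config(seed = 400 + s,
                                        households_per_psu = 20))
    f_all <- fit_lpm(tabs$panel, tabs$exposures, regression_spec(controls = "none"))
    f_ex <- fit_lpm(migration_exclusion(tabs$panel, "drop_movers_and_unknown"),
                    tabs$exposures, regression_spec(controls = "none"))
    unname(f_ex$coefficients["coal_count"] - f_all$coefficients["coal_count"])
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 2 * sd(diffs) / sqrt(length(diffs)) + 1e-4)
})

test_that("diagnostics are pure functions of their inputs", {
  tabs <- generate_panel(small_config(seed = 44))
  w0 <- tabs$panel[tabs$panel$wave == 0, ]
  treated <- tabs$exposures$coal_plants_gained[
    match(w0$district_id, tabs$exposures$district_id)] > 0
  expect_identical(balance_test(w0, treated, c("cough", "urban")),
                   balance_test(w0, treated, c("cough", "urban")))
  cc <- generate_census_changes(small_config(seed = 44), tabs$exposures)
  expect_identical(coef_table(pretrend_regression(cc, "d_imr")),
                   coef_table(pretrend_regression(cc, "d_imr")))
})
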