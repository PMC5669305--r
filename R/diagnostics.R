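#' Baseline balance test by treatment status
#'
#' Compares first-wave means of the requested variables between households in
#' districts that later gained a coal plant and households in districts that
#' did not. Means and their standard errors are computed with clustering (the
#' cluster-robust variance of a group mean is the sum of squared within-group
#' cluster residual sums over the squared group size); the t statistic tests
#' equality of the two group means, with clusters nested within groups.
#'
#' @param panel_wave0 First-wave rows of the panel.
#' @param treated Logical/0-1 vector (per row of `panel_wave0`) marking
#'   households in subsequently treated districts.
#' @param variables Character vector of numeric columns to compare.
#' @param cluster_ids Cluster membership (default: PSU).
#' @return data.frame with one row per variable: `variable`, `mean_group0`,
#'   `se_group0`, `mean_group1`, `se_group1`, `t_stat`.
#' @export
balance_test <- function(panel_wave0, treated, variables,
                         cluster_ids = panel_wave0$psu_id) {
  treated <- as.logical(treated)
  if (!any(treated) || all(treated))
    abort_degenerate("both treatment groups must be non-empty")
  one_group <- function(x, cl) {
    m <- mean(x)
    cl_sums <- rowsum(x - m, as.integer(factor(cl)))[, 1]
    se <- sqrt(sum(cl_sums^2)) / length(x)
    c(mean = m, se = se)
  }
  rows <- lapply(variables, function(v) {
    x <- panel_wave0[[v]]
    if (is.null(x)) abort_usage(sprintf("unknown variable '%s'", v))
    ok <- !is.na(x)
    g0 <- one_group(x[ok & !treated], cluster_ids[ok & !treated])
    g1 <- one_group(x[ok & treated], cluster_ids[ok & treated])
    data.frame(variable = v,
               mean_group0 = g0["mean"], se_group0 = g0["se"],
               mean_group1 = g1["mean"], se_group1 = g1["se"],
               t_stat = (g1["mean"] - g0["mean"]) /
                 sqrt(g0["se"]^2 + g1["se"]^2),
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Pre-program parallel-trends regression on district census changes
#'
#' Regresses a district-level change over the pre-program decade on the
#' number of coal plants subsequently gained (OLS with intercept,
#' heteroskedasticity-robust HC1 standard errors). Under parallel pre-trends
#' the slope should be indistinguishable from zero. With a binary treatment
#' regressor the intercept equals the mean change among districts that did
#' not gain a plant.
#'
#' @param census_changes data.frame from [generate_census_changes()] (or real
#'   data with the same columns).
#' @param outcome Name of the change column, or `"principal_component"` to
#'   use the first principal component of the five change variables (see
#'   [first_principal_component()]).
#' @param treatment `"count"` (default) or `"binary"`.
#' @return A `"coal_fit"` object (coefficients `coal` and `constant`).
#' @export
pretrend_regression <- function(census_changes, outcome,
                                treatment = c("count", "binary")) {
  treatment <- match.arg(treatment)
  if (nrow(census_changes) < 3)
    abort_degenerate("pre-trend regression needs at least 3 districts")
  y <- if (outcome == "principal_component") {
    cols <- c("d_imr", "d_female_literacy", "d_total_literacy",
              "d_sanitation", "d_electricity")
    first_principal_component(as.matrix(census_changes[, cols]))$scores
  } else {
    yv <- census_changes[[outcome]]
    if (is.null(yv)) abort_usage(sprintf("unknown outcome '%s'", outcome))
    yv
  }
  x_raw <- census_changes$coal_plants_gained
  xt <- if (treatment == "binary") as.numeric(x_raw >= 1) else as.numeric(x_raw)
  if (stats::var(xt) == 0)
    abort_degenerate("treatment regressor is constant across districts")
  x <- cbind(coal = xt, constant = 1)
  fit <- ols_dropping_collinear(x, y)
  # HC1 = CR1 with singleton clusters
  v <- cluster_robust_vcov(fit$x_kept, fit$residuals,
                           seq_len(nrow(x)), df_correction = TRUE)
  se <- sqrt(diag(v))
  tstat <- fit$coefficients / se
  structure(list(coefficients = fit$coefficients, se = se, t = tstat,
                 p = 2 * stats::pnorm(-abs(tstat)), vcov = v,
                 treatment = "coal",
                 n_obs = nrow(census_changes), n_units = nrow(census_changes),
                 n_clusters = nrow(census_changes),
                 dropped_collinear = fit$dropped,
                 spec = list(outcome = outcome), model = "pretrend_ols"),
            class = "coal_fit")
}

#' First principal component of standardized change variables
#'
#' Standardizes each column, takes the lead eigenvector of the correlation
#' matrix as the loading vector, and returns the scores (zero mean; variance
#' equal to the lead eigenvalue). The correlation matrix is used because the
#' inputs are on different scales (deaths per 1,000 vs percentage points).
#' The sign is fixed so the loading on `d_total_literacy` (or, if absent, the
#' first column) is positive.
#'
#' @param x Numeric matrix with at least 2 rows and no missing values.
#' @return List with `scores`, `loadings`, `eigenvalue`.
#' @export
first_principal_component <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) abort_usage("need at least 2 rows")
  if (anyNA(x)) abort_missing_data("missing values in principal-component input")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    cc_abort(sprintf("zero-variance column(s): %s",
                     paste(colnames(x)[sds == 0], collapse = ", ")),
             "coalcough_standardization_error")
  z <- scale(x)
  e <- eigen(stats::cor(x), symmetric = TRUE)
  loading <- e$vectors[, 1]
  names(loading) <- colnames(x)
  anchor <- if ("d_total_literacy" %in% colnames(x)) "d_total_literacy" else 1
  if (loading[anchor] < 0) loading <- -loading
  list(scores = as.vector(z %*% loading), loadings = loading,
       eigenvalue = e$values[1])
}

#' Falsification suite: placebo outcomes and the non-coal placebo treatment
#'
#' Re-estimates the base specification with each falsification outcome
#' substituted (by default fever and diarrhea, which coal plants should not
#' affect), and once more on the original outcome with the count of non-coal
#' plants added as a placebo regressor. Any coefficient distinguishable from
#' zero flags a violated identifying assumption.
#'
#' @param panel,exposures As in [fit_lpm()].
#' @param base_spec The specification whose outcome is swapped.
#' @param outcomes Character vector of placebo outcome columns.
#' @param include_noncoal Also fit the non-coal placebo regression?
#' @return Named list of `"coal_fit"` objects (one per placebo outcome, plus
#'   `"noncoal_placebo"` if requested).
#' @export
falsification_suite <- function(panel, exposures,
                                base_spec = regression_spec(),
                                outcomes = c("fever", "diarrhea"),
                                include_noncoal = TRUE) {
  results <- list()
  for (oc in outcomes) {
    sp <- base_spec
    sp$outcome <- oc
    results[[oc]] <- fit_lpm(panel, exposures, sp)
  }
  if (include_noncoal) {
    sp <- base_spec
    sp$extra_terms <- union(sp$extra_terms, "noncoal_count")
    results[["noncoal_placebo"]] <- fit_lpm(panel, exposures, sp)
  }
  results
}

#' Exclude migrant households from the panel
#'
#' Implements the avoidance-behavior robustness filter: households reporting
#' a move within the seven years before either survey wave are removed (in
#' both waves, so the panel stays balanced); the strict rule additionally
#' removes households whose migration status is missing.
#'
#' @param panel Household x wave data.frame with `moved_within_7y`.
#' @param rule `"all"` (no filtering), `"drop_known_movers"`, or
#'   `"drop_movers_and_unknown"`.
#' @return The filtered panel (possibly empty).
#' @export
migration_exclusion <- function(panel,
                                rule = c("all", "drop_known_movers",
                                         "drop_movers_and_unknown")) {
  rule <- match.arg(rule)
  if (rule == "all") return(panel)
  if (!"moved_within_7y" %in% names(panel))
    abort_usage("panel lacks a moved_within_7y column")
  mv <- panel$moved_within_7y
  hh <- panel$household_id
  mover_ids <- unique(hh[!is.na(mv) & mv == 1])
  drop_ids <- mover_ids
  if (rule == "drop_movers_and_unknown")
    drop_ids <- union(drop_ids, unique(hh[is.na(mv)]))
  panel[!(hh %in% drop_ids), , drop = FALSE]
}

#' Electrification outcomes check
#'
#' Fits the fixed-effects model with electricity access and hours as
#' outcomes, to verify that gaining a coal plant is not associated with
#' differential electrification (which could otherwise confound the health
#' result).
#'
#' @param panel,exposures As in [fit_lpm()].
#' @param base_spec Specification template (outcome is replaced).
#' @return Named list of `"coal_fit"` objects for `has_electricity` and
#'   `electricity_hours`.
#' @export
electrification_check <- function(panel, exposures,
                                  base_spec = regression_spec(controls = "none")) {
  out <- list()
  for (oc in c("has_electricity", "electricity_hours")) {
    sp <- base_spec
    sp$outcome <- oc
    out[[oc]] <- fit_lpm(panel, exposures, sp)
  }
  out
}
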