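#' Specify a fixed-effects linear-probability regression
#'
#' Describes one column of the robustness battery: which binary outcome is
#' regressed on the coal-plant exposure, how the district plant count is
#' transformed, at which level the fixed effects are absorbed, which control
#' block enters, optional interaction / placebo terms, the sample filter, and
#' the clustering level for the sandwich variance.
#'
#' @param outcome Outcome column name (`"cough"`, `"fever"`, `"diarrhea"`, or
#'   any binary column in the panel).
#' @param treatment_transform One of `"count"` (plants gained), `"topcoded"`
#'   (count capped at `topcode_at`), `"binary"` (indicator for gaining any
#'   plant), `"demeaned_count"` (count minus its observation-weighted mean).
#' @param topcode_at Cap for the top-coded transform (default 4).
#' @param fe_level `"household"` or `"psu"`; the fixed effect absorbed by
#'   within-group demeaning. With household fixed effects the time-invariant
#'   `urban` control is absorbed and therefore excluded from the control set.
#' @param controls `"none"`, `"demographic"` (log consumption per capita,
#'   urban residence, household size) or `"full"` (demographic plus cooking
#'   fuel, dung use, separate kitchen, electricity access and hours).
#' @param extra_terms Character subset of `"urban_x_round"` (urban-specific
#'   time trend), `"treatment_x_urban"` (requires the demeaned treatment
#'   transform; both factors are demeaned to preserve comparability of the
#'   main effect), `"noncoal_count"` (placebo count of non-coal plants).
#' @param sample_filter `"all"`, `"nonmovers"` (drop households reporting a
#'   move), `"nonmovers_strict"` (additionally drop households whose move
#'   status is missing), or `"capacity_le"` (drop districts whose capacity
#'   gain exceeds `capacity_cap_mw`).
#' @param capacity_cap_mw MW cap used by the `"capacity_le"` filter.
#' @param cluster_level `"psu"` (the survey's first-stage sampling unit;
#'   default) or `"district"`.
#' @param p_reference `"normal"` (large-cluster asymptotics; default) or
#'   `"t"` (Student t with G-1 degrees of freedom).
#' @return An object of class `"regression_spec"`.
#' @export
regression_spec <- function(outcome = "cough",
                            treatment_transform = c("count", "topcoded",
                                                    "binary", "demeaned_count"),
                            topcode_at = 4,
                            fe_level = c("household", "psu"),
                            controls = c("none", "demographic", "full"),
                            extra_terms = character(),
                            sample_filter = c("all", "nonmovers",
                                              "nonmovers_strict", "capacity_le"),
                            capacity_cap_mw = NULL,
                            cluster_level = c("psu", "district"),
                            p_reference = c("normal", "t")) {
  spec <- list(
    outcome = outcome,
    treatment_transform = match.arg(treatment_transform),
    topcode_at = topcode_at,
    fe_level = match.arg(fe_level),
    controls = match.arg(controls),
    extra_terms = extra_terms,
    sample_filter = match.arg(sample_filter),
    capacity_cap_mw = capacity_cap_mw,
    cluster_level = match.arg(cluster_level),
    p_reference = match.arg(p_reference)
  )
  known <- c("urban_x_round", "treatment_x_urban", "noncoal_count")
  if (!all(spec$extra_terms %in% known))
    abort_usage(sprintf("unknown extra term(s): %s",
                        paste(setdiff(spec$extra_terms, known), collapse = ", ")))
  if ("treatment_x_urban" %in% spec$extra_terms &&
      spec$treatment_transform != "demeaned_count")
    abort_usage("treatment_x_urban requires treatment_transform = 'demeaned_count'")
  if (spec$sample_filter == "capacity_le" &&
      (is.null(capacity_cap_mw) || capacity_cap_mw <= 0))
    abort_usage("capacity_le filter requires a positive capacity_cap_mw")
  class(spec) <- "regression_spec"
  spec
}

#' Transform the district plant count into the regression treatment variable
#'
#' @param exposures District exposure table with `coal_plants_gained`.
#' @param transform `"count"`, `"topcoded"`, `"binary"` or
#'   `"demeaned_count"`.
#' @param topcode_at Cap for `"topcoded"`.
#' @param weights Observation weights used for the `"demeaned_count"` mean
#'   (e.g. households per district); defaults to equal weights.
#' @return Numeric vector of per-district treatment values (before the
#'   interaction with the second-wave indicator).
#' @export
transform_treatment <- function(exposures, transform, topcode_at = 4,
                                weights = NULL) {
  count <- exposures$coal_plants_gained
  switch(transform,
    count = as.numeric(count),
    topcoded = pmin(as.numeric(count), topcode_at),
    binary = as.numeric(count >= 1),
    demeaned_count = {
      w <- weights %||% rep(1, length(count))
      as.numeric(count) - sum(w * count) / sum(w)
    },
    abort_usage(sprintf("unknown treatment transform '%s'", transform))
  )
}

#' Within-group (fixed effect) demeaning
#'
#' Subtracts the group mean of each requested column within each fixed-effect
#' group, the standard absorption of unit intercepts in panel regression.
#' Groups of size one become all-zero rows (they carry no within-information
#' but are retained so observation counts match the input).
#'
#' @param panel Household x wave data.frame.
#' @param fe_level `"household"` or `"psu"` (uses `household_id` / `psu_id`).
#' @param columns Character vector of numeric columns to demean.
#' @return A matrix of demeaned columns in input row order.
#' @export
within_transform <- function(panel, fe_level, columns) {
  id_col <- switch(fe_level, household = "household_id", psu = "psu_id",
                   abort_usage(sprintf("unknown fe_level '%s'", fe_level)))
  x <- as.matrix(panel[, columns, drop = FALSE])
  if (anyNA(x))
    abort_missing_data(sprintf(
      "missing values in column(s): %s",
      paste(columns[colSums(is.na(x)) > 0], collapse = ", ")))
  g <- match(panel[[id_col]], unique(panel[[id_col]]))
  demean_by_group(x, g)
}

#' Cluster-robust (CR1) sandwich covariance matrix
#'
#' Computes the sandwich estimator
#' \deqn{(X'X)^{-1} \Big(\sum_g X_g' e_g e_g' X_g\Big) (X'X)^{-1}}
#' over clusters `g`, optionally scaled by the CR1 finite-sample factor
#' `G/(G-1) * (N-1)/(N-K)` where `G` is the number of clusters, `N` the
#' number of observations and `K` the model rank (including any absorbed
#' fixed-effect groups, passed via `k_absorbed`). With every observation its
#' own cluster this reduces to the heteroskedasticity-robust (HC) sandwich.
#'
#' @param design Numeric design matrix (already demeaned if fixed effects
#'   are absorbed); must be full column rank.
#' @param residuals Residual vector.
#' @param cluster_ids Cluster membership vector (any type; coerced to
#'   factor). Invariant to relabeling and observation order.
#' @param df_correction Apply the CR1 factor? Default `TRUE`.
#' @param k_absorbed Number of parameters absorbed by demeaning (counted in
#'   `K`). Default 0.
#' @return Symmetric positive semidefinite covariance matrix.
#' @export
cluster_robust_vcov <- function(design, residuals, cluster_ids,
                                df_correction = TRUE, k_absorbed = 0) {
  design <- as.matrix(design)
  n <- nrow(design)
  k <- ncol(design)
  qr_x <- qr(design)
  if (qr_x$rank < k) {
    null_cols <- colnames(design)[qr_x$pivot[(qr_x$rank + 1):k]] %||%
      qr_x$pivot[(qr_x$rank + 1):k]
    abort_rank(sprintf("design matrix is rank deficient; null-space column(s): %s",
                       paste(null_cols, collapse = ", ")))
  }
  bread <- chol2inv(qr.R(qr_x)[seq_len(k), seq_len(k), drop = FALSE])
  g <- as.integer(factor(cluster_ids))
  score_sums <- rowsum(design * residuals, g)
  meat <- crossprod(score_sums)
  v <- bread %*% meat %*% bread
  if (df_correction) {
    n_g <- max(g)
    k_total <- k + k_absorbed
    v <- v * (n_g / (n_g - 1)) * ((n - 1) / (n - k_total))
  }
  v <- (v + t(v)) / 2
  dimnames(v) <- list(colnames(design), colnames(design))
  v
}

# Control column sets; urban is excluded under household FE (time-invariant,
# absorbed by the fixed effect).
control_columns <- function(controls, fe_level) {
  demo <- c("ln_cons_pc", "urban", "hh_size")
  resp <- c("clean_fuel", "dung", "separate_kitchen",
            "has_electricity", "electricity_hours")
  cols <- switch(controls, none = character(), demographic = demo,
                 full = c(demo, resp))
  if (fe_level == "household") cols <- setdiff(cols, "urban")
  cols
}

apply_sample_filter <- function(panel, exposures, spec) {
  switch(spec$sample_filter,
    all = panel,
    nonmovers = migration_exclusion(panel, "drop_known_movers"),
    nonmovers_strict = migration_exclusion(panel, "drop_movers_and_unknown"),
    capacity_le = {
      cap <- spec$capacity_cap_mw
      keep_d <- exposures$district_id[exposures$capacity_gained_mw <= cap]
      out <- panel[panel$district_id %in% keep_d, , drop = FALSE]
      treated_kept <- exposures$capacity_gained_mw > 0 &
        exposures$capacity_gained_mw <= cap
      if (!any(treated_kept))
        abort_degenerate("capacity cap excludes every exposed district")
      out
    })
}

# Build the observation-level design pieces shared by the OLS and logit
# fitters. Returns list(y, x (matrix), cluster, fe_id, panel).
build_design <- function(panel, exposures, spec,
                         treatment_values = NULL,
                         treatment_names = NULL) {
  if (!spec$outcome %in% names(panel))
    abort_usage(sprintf("outcome column '%s' not in panel", spec$outcome))
  if (anyDuplicated(paste(panel$household_id, panel$wave)))
    abort_integrity("duplicated household x wave rows")
  panel <- apply_sample_filter(panel, exposures, spec)
  if (length(unique(panel$wave)) < 2)
    abort_degenerate("panel must contain both survey waves")

  d_idx <- match(panel$district_id, exposures$district_id)
  if (anyNA(d_idx))
    abort_integrity("panel contains district ids absent from exposure table")

  if (is.null(treatment_values)) {
    hh_weights <- as.vector(table(factor(panel$district_id,
                                         levels = exposures$district_id)))
    tt <- transform_treatment(exposures, spec$treatment_transform,
                              spec$topcode_at, weights = hh_weights)
    treatment_values <- matrix(tt, ncol = 1)
    treatment_names <- paste0("coal_", spec$treatment_transform)
  }
  treatment_values <- as.matrix(treatment_values)
  x_treat <- treatment_values[d_idx, , drop = FALSE] * panel$wave
  colnames(x_treat) <- treatment_names

  x <- cbind(x_treat, round_2012 = as.numeric(panel$wave))

  if ("urban_x_round" %in% spec$extra_terms)
    x <- cbind(x, urban_x_round = panel$urban * panel$wave)
  if ("treatment_x_urban" %in% spec$extra_terms) {
    urban_dm <- panel$urban - mean(panel$urban)
    x <- cbind(x, treatment_x_urban = x_treat[, 1] * urban_dm)
  }
  if ("noncoal_count" %in% spec$extra_terms) {
    nc <- exposures$noncoal_plants_gained[d_idx] * panel$wave
    x <- cbind(x, noncoal_count = as.numeric(nc))
  }

  ctrl <- control_columns(spec$controls, spec$fe_level)
  if (length(ctrl)) {
    cm <- as.matrix(panel[, ctrl, drop = FALSE])
    if (anyNA(cm))
      abort_missing_data(sprintf(
        "missing values in control column(s): %s",
        paste(ctrl[colSums(is.na(cm)) > 0], collapse = ", ")))
    x <- cbind(x, cm)
  }

  cluster <- switch(spec$cluster_level, psu = panel$psu_id,
                    district = panel$district_id)
  fe_id <- switch(spec$fe_level, household = panel$household_id,
                  psu = panel$psu_id)
  list(y = as.numeric(panel[[spec$outcome]]), x = x, cluster = cluster,
       fe_id = fe_id, panel = panel)
}

#' Fit the fixed-effects linear-probability difference-in-differences model
#'
#' Estimates, by within-group OLS, the linear probability model
#' \deqn{y_{ipdt} = \beta x_{dt} + \theta' z_{it} + \alpha_{ipd} + \gamma_t + \varepsilon_{ipdt}}
#' where `y` is a binary morbidity indicator, `x` is the (transformed)
#' district count of coal plants gained interacted with the second-wave
#' indicator, `z` are optional household controls, `alpha` a household or
#' PSU fixed effect absorbed by demeaning, and `gamma` the survey-round
#' fixed effect. Standard errors are cluster-robust (CR1; see
#' [cluster_robust_vcov()]).
#'
#' Collinear columns are dropped (QR pivoting) and reported in
#' `dropped_collinear`; if the treatment column itself is dropped, a
#' degenerate-design error names it.
#'
#' @param panel Household x wave data.frame (see [generate_panel()]).
#' @param exposures District exposure table.
#' @param spec A [regression_spec()].
#' @return An object of class `"coal_fit"` with elements `coefficients`,
#'   `se`, `t`, `p`, `vcov`, `n_obs`, `n_units`, `n_clusters`,
#'   `dropped_collinear`, `spec`.
#' @export
#' @examples
#' tabs <- generate_panel(synth_config(n_districts = 40,
#'   n_treated_districts = 6, psus_per_district = 2, households_per_psu = 8))
#' fit <- fit_lpm(tabs$panel, tabs$exposures, regression_spec())
#' print(fit)
fit_lpm <- function(panel, exposures, spec = regression_spec()) {
  d <- build_design(panel, exposures, spec)
  fe_fac <- match(d$fe_id, unique(d$fe_id))
  n_units <- max(fe_fac)
  xd <- demean_by_group(d$x, fe_fac)
  yd <- demean_by_group(d$y, fe_fac)

  rd <- match("round_2012", colnames(d$x))
  prio <- c(rd, setdiff(seq_len(ncol(d$x)), rd))
  fit <- ols_dropping_collinear(xd, yd, priority = prio)
  treat_name <- colnames(d$x)[1]
  if (treat_name %in% fit$dropped)
    abort_degenerate(sprintf(
      "treatment column '%s' is collinear with the fixed effects/round effect",
      treat_name))

  g <- as.integer(factor(d$cluster))
  if (max(g) < 2)
    abort_inference("fewer than 2 clusters; cluster-robust inference impossible")

  # FE groups are nested within clusters, so the absorbed intercepts do not
  # enter the finite-sample correction (k_absorbed = 0); counting them would
  # roughly double the variance in a two-period panel.
  v <- cluster_robust_vcov(fit$x_kept, fit$residuals, d$cluster,
                           df_correction = TRUE, k_absorbed = 0)
  se <- sqrt(diag(v))
  tstat <- fit$coefficients / se
  n_g <- max(g)
  p <- if (spec$p_reference == "t") {
    2 * stats::pt(-abs(tstat), df = n_g - 1)
  } else {
    2 * stats::pnorm(-abs(tstat))
  }

  structure(list(
    coefficients = fit$coefficients,
    se = se, t = tstat, p = p, vcov = v,
    treatment = treat_name,
    n_obs = length(d$y), n_units = n_units, n_clusters = n_g,
    dropped_collinear = fit$dropped,
    residuals = fit$residuals,
    spec = spec, model = "fe_ols"
  ), class = "coal_fit")
}

# OLS dropping collinear columns greedily in `priority` order (earlier
# columns win a collinearity tie). The round fixed effect is given priority
# over the treatment by the callers, so a treatment collinear with it is
# reported as dropped rather than silently absorbing the time trend.
ols_dropping_collinear <- function(x, y, tol = 1e-9,
                                   priority = seq_len(ncol(x))) {
  k <- ncol(x)
  qr_full <- qr(x, tol = tol)
  if (qr_full$rank == k) {
    kept <- rep(TRUE, k)
  } else {
    kept <- logical(k)
    cur_rank <- 0L
    for (j in priority) {
      trial <- kept
      trial[j] <- TRUE
      r <- qr(x[, trial, drop = FALSE], tol = tol)$rank
      if (r > cur_rank) {
        kept <- trial
        cur_rank <- r
      }
    }
  }
  if (!any(kept)) abort_degenerate("design has no non-degenerate columns")
  dropped <- colnames(x)[!kept]
  x_kept <- x[, kept, drop = FALSE]
  beta <- qr.coef(qr(x_kept, tol = tol), y)
  resid <- y - as.vector(x_kept %*% beta)
  list(coefficients = beta, residuals = resid, x_kept = x_kept,
       dropped = dropped)
}

#' @export
print.coal_fit <- function(x, ...) {
  cat(sprintf("%s: outcome '%s', n = %s, %s = %s, clusters = %s\n",
              switch(x$model, fe_ols = "Fixed-effects LPM",
                     clogit = "Conditional fixed-effects logit", x$model),
              x$spec$outcome %||% "?",
              format(x$n_obs, big.mark = ","),
              if (identical(x$model, "clogit")) "switchers" else "FE groups",
              format(x$n_units, big.mark = ","),
              format(x$n_clusters, big.mark = ",")))
  tab <- data.frame(estimate = x$coefficients, se = x$se, t = x$t, p = x$p)
  if (!is.null(x$odds_ratio)) {
    tab$odds_ratio <- x$odds_ratio
    tab$or_se <- x$or_se
  }
  print(format(tab, digits = 4))
  if (length(x$dropped_collinear))
    cat("dropped (collinear):", paste(x$dropped_collinear, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a fitted model into a one-row-per-coefficient data.frame
#' @param fit A `"coal_fit"` object.
#' @return data.frame with `term`, `estimate`, `se`, `t`, `p`.
#' @export
coef_table <- function(fit) {
  stopifnot(inherits(fit, "coal_fit"))
  data.frame(term = names(fit$coefficients),
             estimate = unname(fit$coefficients),
             se = unname(fit$se), t = unname(fit$t), p = unname(fit$p),
             row.names = NULL)
}

#' Two-period conditional fixed-effects logit
#'
#' Maximizes the conditional likelihood of the fixed-effects logit for a
#' binary outcome observed in exactly two waves per household. Households
#' whose outcome does not change between waves contribute a constant factor
#' to the conditional likelihood and are excluded; for the switchers the
#' conditional likelihood reduces to a logistic model of "switched up"
#' (0 at wave 1, 1 at wave 2) on the within-household covariate differences
#' (which include the round effect as a constant difference). Estimated by
#' Newton-Raphson on the analytic score (tolerance 1e-9 on the gradient
#' norm, at most 100 iterations). Coefficients are reported both on the log
#' scale and as odds ratios with delta-method standard errors.
#'
#' @inheritParams fit_lpm
#' @return A `"coal_fit"` object with additional `odds_ratio` and `or_se`
#'   elements and `n_units` equal to the number of switcher households.
#' @export
fit_conditional_logit <- function(panel, exposures, spec = regression_spec()) {
  d <- build_design(panel, exposures, spec)
  y <- d$y
  if (!all(y %in% c(0, 1)))
    abort_usage("conditional logit requires a binary outcome")

  hh <- factor(d$panel$household_id)
  if (!all(tabulate(hh) == 2))
    abort_usage("conditional logit requires exactly two waves per household")
  ord <- order(hh, d$panel$wave)
  y <- y[ord]; x <- d$x[ord, , drop = FALSE]
  hh_o <- hh[ord]; cl <- d$cluster[ord]
  i2 <- seq(2, length(y), by = 2); i1 <- i2 - 1

  dy <- y[i2] - y[i1]
  switchers <- dy != 0
  if (!any(switchers))
    abort_inestimable("no household changes outcome between waves; conditional likelihood is flat")
  dx <- (x[i2, , drop = FALSE] - x[i1, , drop = FALSE])[switchers, , drop = FALSE]
  z <- as.numeric(dy[switchers] == 1)
  cl_hh <- cl[i1][switchers]

  # Drop constant-zero / collinear difference columns
  qr_dx <- qr(dx)
  kept_idx <- sort(qr_dx$pivot[seq_len(qr_dx$rank)])
  dropped <- setdiff(colnames(dx), colnames(dx)[kept_idx])
  dx <- dx[, kept_idx, drop = FALSE]
  treat_name <- colnames(d$x)[1]
  if (treat_name %in% dropped)
    abort_degenerate(sprintf("treatment column '%s' has no within-household variation among switchers",
                             treat_name))

  beta <- rep(0, ncol(dx))
  for (iter in seq_len(100)) {
    eta <- as.vector(dx %*% beta)
    mu <- stats::plogis(eta)
    grad <- crossprod(dx, z - mu)
    w <- mu * (1 - mu)
    hess <- crossprod(dx * w, dx)
    if (sqrt(sum(grad^2)) < 1e-9) break
    step <- tryCatch(solve(hess, grad), error = function(e)
      abort_rank("singular Hessian in conditional logit"))
    beta <- beta + as.vector(step)
    if (iter == 100 && sqrt(sum(grad^2)) >= 1e-9)
      abort_convergence(sprintf(
        "conditional logit did not converge in 100 iterations (gradient norm %.3g)",
        sqrt(sum(grad^2))))
  }
  eta <- as.vector(dx %*% beta)
  mu <- stats::plogis(eta)
  hess <- crossprod(dx * (mu * (1 - mu)), dx)
  v <- solve(hess)
  se <- sqrt(diag(v))
  names(beta) <- names(se) <- colnames(dx)
  dimnames(v) <- list(colnames(dx), colnames(dx))
  tstat <- beta / se
  p <- 2 * stats::pnorm(-abs(tstat))
  or <- exp(beta)

  structure(list(
    coefficients = beta, se = se, t = tstat, p = p, vcov = v,
    odds_ratio = or, or_se = or * se,
    loglik = sum(z * eta - log1p(exp(eta))),
    treatment = treat_name,
    n_obs = length(d$y), n_units = sum(switchers),
    n_clusters = length(unique(cl_hh)),
    dropped_collinear = dropped,
    spec = spec, model = "clogit"
  ), class = "coal_fit")
}
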