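#' Capacity dose-response regression
#'
#' Replaces the plant-count treatment with a continuous dose in gained
#' generating capacity: `capacity / capacity_scale` (and its square for the
#' quadratic form), interacted with the second-wave indicator, in the same
#' fixed-effects linear-probability framework as [fit_lpm()]. An optional
#' capacity cap restricts the sample to districts whose gain is at or below
#' the cap (entire districts above the cap are dropped) while retaining all
#' zero-exposure districts — the linear fit on the lower 90% of exposure is
#' the headline dose-response number, the quadratic on the full sample probes
#' curvature.
#'
#' @param panel,exposures As in [fit_lpm()].
#' @param spec A [regression_spec()] providing outcome, fixed-effect level,
#'   controls and clustering (its treatment transform is ignored).
#' @param form `"linear"` or `"quadratic"`.
#' @param capacity_cap_mw Optional cap in MW; must be positive.
#' @param capacity_scale MW per coefficient unit (default 1,000: the linear
#'   coefficient is the probability effect of 1,000 MW).
#' @return A `"coal_fit"` object; treatment terms are `capacity_dose` and,
#'   for the quadratic form, `capacity_dose_sq`.
#' @export
fit_dose_response <- function(panel, exposures, spec = regression_spec(),
                              form = c("linear", "quadratic"),
                              capacity_cap_mw = NULL,
                              capacity_scale = 1000) {
  form <- match.arg(form)
  if (!"capacity_gained_mw" %in% names(exposures))
    abort_usage("exposure table lacks capacity_gained_mw")
  if (!is.null(capacity_cap_mw)) {
    if (capacity_cap_mw <= 0) abort_usage("capacity cap must be positive")
    spec$sample_filter <- "capacity_le"
    spec$capacity_cap_mw <- capacity_cap_mw
  }
  caps <- exposures$capacity_gained_mw
  kept <- if (is.null(capacity_cap_mw)) caps else caps[caps <= capacity_cap_mw]
  if (all(kept == 0))
    abort_degenerate("no exposed districts remain; capacity dose is degenerate")
  if (form == "quadratic" && length(unique(kept[kept > 0])) < 2)
    abort_degenerate("quadratic dose needs at least 2 distinct positive capacities")

  dose <- caps / capacity_scale
  tv <- if (form == "linear") {
    matrix(dose, ncol = 1)
  } else {
    cbind(dose, dose^2)
  }
  tn <- if (form == "linear") "capacity_dose" else
    c("capacity_dose", "capacity_dose_sq")

  d <- build_design(panel, exposures, spec,
                    treatment_values = tv, treatment_names = tn)
  fe_fac <- match(d$fe_id, unique(d$fe_id))
  n_units <- max(fe_fac)
  xd <- demean_by_group(d$x, fe_fac)
  yd <- demean_by_group(d$y, fe_fac)
  rd <- match("round_2012", colnames(d$x))
  prio <- c(rd, setdiff(seq_len(ncol(d$x)), rd))
  fit <- ols_dropping_collinear(xd, yd, priority = prio)
  if (tn[1] %in% fit$dropped)
    abort_degenerate("capacity dose is collinear with the fixed effects")
  v <- cluster_robust_vcov(fit$x_kept, fit$residuals, d$cluster,
                           df_correction = TRUE, k_absorbed = 0)
  se <- sqrt(diag(v))
  tstat <- fit$coefficients / se
  structure(list(coefficients = fit$coefficients, se = se, t = tstat,
                 p = 2 * stats::pnorm(-abs(tstat)), vcov = v,
                 treatment = tn[1],
                 n_obs = length(d$y), n_units = n_units,
                 n_clusters = length(unique(d$cluster)),
                 dropped_collinear = fit$dropped,
                 spec = spec, model = "fe_ols",
                 dose_form = form, capacity_scale = capacity_scale,
                 capacity_cap_mw = capacity_cap_mw),
            class = "coal_fit")
}

#' Household-weighted capacity coverage
#'
#' For each threshold, the fraction of households in exposed districts whose
#' district's capacity gain is at or below the threshold — the
#' household-weighted empirical CDF of the capacity distribution among the
#' exposed.
#'
#' @param exposures District exposure table.
#' @param panel Household x wave panel (used for household weights; wave-0
#'   rows are used so each household counts once).
#' @param thresholds Positive MW thresholds.
#' @return Named numeric vector of coverage fractions.
#' @export
capacity_coverage <- function(exposures, panel, thresholds = c(600, 1000)) {
  if (any(thresholds <= 0)) abort_usage("thresholds must be positive")
  hh <- panel[panel$wave == min(panel$wave), , drop = FALSE]
  cap_hh <- exposures$capacity_gained_mw[match(hh$district_id,
                                               exposures$district_id)]
  exposed <- cap_hh > 0
  if (!any(exposed)) abort_degenerate("no exposed households")
  out <- vapply(thresholds, function(th) mean(cap_hh[exposed] <= th),
                numeric(1))
  names(out) <- paste0("le_", thresholds, "mw")
  out
}
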