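#' Configuration for the synthetic two-wave household panel generator
#'
#' Builds the parameter set for [generate_panel()] and
#' [generate_census_changes()]. Defaults emulate the structure of a national
#' two-wave Indian household survey matched to a registry of newly
#' commissioned power plants: 389 districts of which 46 gain at least one
#' coal plant, roughly 2,400 primary sampling units (PSUs) nesting in
#' districts and households nesting in PSUs, a household cough prevalence of
#' about 9.8% with a 1.6 percentage-point secular decline between waves, and
#' a per-plant treatment effect on cough of +1 percentage point that applies
#' only in the second wave. Fever and diarrhea are generated with a zero
#' coal-plant coefficient, as are plants other than coal, so they serve as
#' built-in falsification outcomes.
#'
#' The outcome model is a linear probability process: for household `i` in
#' district `d` at wave `t`,
#' `p_it = baseline + alpha_i + controls + trend * t + beta * x_dt`,
#' clipped to `[0, 1]`, with `y_it ~ Bernoulli(p_it)`. `alpha_i` is a
#' zero-mean household effect held fixed across waves; control variables
#' enter centered so `baseline` is the wave-1 prevalence. `x_dt` is the
#' district's count of coal plants gained, times the second-wave indicator.
#'
#' @param n_districts Number of districts.
#' @param n_treated_districts Number of districts gaining at least one coal
#'   plant. Must not exceed `n_districts`.
#' @param psus_per_district PSUs sampled per district.
#' @param households_per_psu Households per PSU.
#' @param plant_count_weights Named probability weights over the number of
#'   coal plants gained by a treated district.
#' @param capacity_mix Named probability weights over district-level MW of
#'   capacity gained; names are MW values. The default places over half the
#'   mass at 250/300/500 MW, 80% at or below 600 MW and 90% at or below
#'   1,000 MW, with a tail to 1,980 MW.
#' @param capacity_assignment `"quota"` (default) assigns capacities to
#'   treated districts by largest-remainder proportional quota with a seeded
#'   shuffle, so the configured mix holds exactly in every realization;
#'   `"sample"` draws them independently.
#' @param beta_cough Cough probability effect per coal plant (second wave).
#' @param secular_trend_cough,secular_trend_fever,secular_trend_diarrhea
#'   Wave-2 shift in each outcome's probability.
#' @param baseline_cough,baseline_fever,baseline_diarrhea Wave-1 prevalences.
#' @param beta_fever,beta_diarrhea Per-plant effects on the falsification
#'   outcomes (0 by default).
#' @param beta_noncoal Effect of a non-coal plant on cough (0 by default).
#' @param beta_capacity,beta_capacity2 If non-`NULL`, the cough treatment
#'   term becomes `beta_capacity * (MW/capacity_scale) + beta_capacity2 *
#'   (MW/capacity_scale)^2` instead of `beta_cough * plants`, for
#'   dose-response studies.
#' @param capacity_scale MW per unit of the capacity dose (default 1,000).
#' @param noncoal_district_fraction Fraction of districts gaining a non-coal
#'   plant (independent of coal treatment).
#' @param migration_fraction Per-wave probability that a household reports
#'   having moved within the last seven years.
#' @param migration_missing_fraction Probability the migration answer is
#'   missing.
#' @param migration_treatment_shift Added to `migration_fraction` in treated
#'   districts (0 by default; set positive to emulate confounded migration
#'   when testing the exclusion logic).
#' @param coef_ln_cons,coef_hh_size,coef_urban,coef_clean_fuel,coef_dung,coef_separate_kitchen,coef_electricity,coef_electricity_hours
#'   Linear-probability coefficients of the (centered) controls on cough.
#' @param household_effect_sd Standard deviation of the household effect.
#' @param urban_fraction Fraction of PSUs classified urban (urban status is
#'   constant within PSU and across waves).
#' @param seed Integer seed; identical configurations with identical seeds
#'   reproduce the tables bit for bit.
#'
#' @return An object of class `"synth_config"` (a validated list).
#' @seealso [generate_panel()], [generate_census_changes()]
#' @export
#' @examples
#' cfg <- synth_config(n_districts = 50, n_treated_districts = 6,
#'                     psus_per_district = 2, households_per_psu = 5)
#' tabs <- generate_panel(cfg)
#' table(tabs$exposures$coal_plants_gained > 0)
synth_config <- function(n_districts = 389L,
                         n_treated_districts = 46L,
                         psus_per_district = 6L,
                         households_per_psu = 17L,
                         plant_count_weights = c("1" = 0.70, "2" = 0.20,
                                                 "3" = 0.05, "4" = 0.05),
                         capacity_mix = c("250" = 0.22, "300" = 0.18,
                                          "500" = 0.18, "600" = 0.22,
                                          "990" = 0.10, "1200" = 0.05,
                                          "1980" = 0.05),
                         capacity_assignment = c("quota", "sample"),
                         beta_cough = 0.01,
                         secular_trend_cough = -0.016,
                         baseline_cough = 0.098,
                         baseline_fever = 0.488,
                         secular_trend_fever = 0.127,
                         baseline_diarrhea = 0.046,
                         secular_trend_diarrhea = -0.005,
                         beta_fever = 0,
                         beta_diarrhea = 0,
                         beta_noncoal = 0,
                         beta_capacity = NULL,
                         beta_capacity2 = NULL,
                         capacity_scale = 1000,
                         noncoal_district_fraction = 0.08,
                         migration_fraction = 0.015,
                         migration_missing_fraction = 0.002,
                         migration_treatment_shift = 0,
                         coef_ln_cons = -0.004,
                         coef_hh_size = 0.002,
                         coef_urban = 0.008,
                         coef_clean_fuel = -0.010,
                         coef_dung = 0.012,
                         coef_separate_kitchen = -0.005,
                         coef_electricity = 0,
                         coef_electricity_hours = 0,
                         household_effect_sd = 0.03,
                         urban_fraction = 0.30,
                         seed = 1L) {
  capacity_assignment <- match.arg(capacity_assignment)
  cfg <- as.list(environment())
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  if (cfg$n_treated_districts > cfg$n_districts)
    abort_invalid_config("n_treated_districts exceeds n_districts")
  if (cfg$n_districts < 1 || cfg$psus_per_district < 1 ||
      cfg$households_per_psu < 1)
    abort_invalid_config("counts must be positive")
  probs <- c(cfg$baseline_cough, cfg$baseline_fever, cfg$baseline_diarrhea,
             cfg$migration_fraction, cfg$migration_missing_fraction,
             cfg$urban_fraction, cfg$noncoal_district_fraction)
  if (any(probs < 0 | probs > 1))
    abort_invalid_config("all probabilities must lie in [0, 1]")
  for (w in list(cfg$plant_count_weights, cfg$capacity_mix)) {
    if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
      abort_invalid_config("probability weights must be nonnegative and sum to 1")
  }
  if (is.null(names(cfg$capacity_mix)) ||
      any(is.na(as.numeric(names(cfg$capacity_mix)))))
    abort_invalid_config("capacity_mix must be named by MW values")
  if (cfg$household_effect_sd < 0)
    abort_invalid_config("household_effect_sd must be nonnegative")
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic panel configuration\n")
  cat(sprintf("  districts: %d (%d gaining coal plants)\n",
              x$n_districts, x$n_treated_districts))
  cat(sprintf("  PSUs/district: %d, households/PSU: %d (%d households)\n",
              x$psus_per_district, x$households_per_psu,
              x$n_districts * x$psus_per_district * x$households_per_psu))
  cat(sprintf("  cough: baseline %.3f, trend %+.3f, effect/plant %+.3f\n",
              x$baseline_cough, x$secular_trend_cough, x$beta_cough))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# Largest-remainder proportional allocation of `n` slots to `weights`.
quota_counts <- function(weights, n) {
  q <- weights * n
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a synthetic two-wave household panel and district exposure table
#'
#' Draws a seeded synthetic panel with the nested district / PSU / household
#' structure, binary morbidity outcomes generated by the linear-probability
#' process described in [synth_config()], household-level controls, and a
#' district exposure table recording coal plants gained, non-coal plants
#' gained and MW of capacity gained between the waves. Treatment enters only
#' in the second wave; exactly `n_treated_districts` districts gain at least
#' one coal plant.
#'
#' @param config A [synth_config()] object.
#' @return A list with elements `panel` (one row per household x wave, see
#'   Details) and `exposures` (one row per district).
#' @details The panel columns are: `household_id`, `psu_id`, `district_id`,
#'   `wave` (0/1), `cough`, `fever`, `diarrhea` (0/1), `ln_cons_pc`,
#'   `hh_size`, `urban`, `clean_fuel`, `dung`, `separate_kitchen`,
#'   `has_electricity`, `electricity_hours`, `moved_within_7y` (0/1 or NA).
#'   If more than 1% of implied outcome probabilities fall outside `[0, 1]`
#'   before clipping, the configuration is rejected with an error.
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  set.seed(config$seed)

  n_d <- config$n_districts
  n_psu <- n_d * config$psus_per_district
  n_hh <- n_psu * config$households_per_psu

  district_of_psu <- rep(seq_len(n_d), each = config$psus_per_district)
  psu_of_hh <- rep(seq_len(n_psu), each = config$households_per_psu)
  district_of_hh <- district_of_psu[psu_of_hh]

  exposures <- generate_exposures(config)
  plants_hh <- exposures$coal_plants_gained[district_of_hh]
  noncoal_hh <- exposures$noncoal_plants_gained[district_of_hh]
  capacity_hh <- exposures$capacity_gained_mw[district_of_hh]

  urban_psu <- stats::rbinom(n_psu, 1, config$urban_fraction)
  urban <- urban_psu[psu_of_hh]

  # Household-level time-invariant draws. The household-effect dispersion is
  # anchored at a 9.8% reference prevalence and shrinks proportionally for
  # rarer outcomes, so low-baseline outcomes do not generate probabilities
  # below zero.
  alpha_sd <- function(baseline)
    config$household_effect_sd * min(1, baseline / 0.098)
  alpha_c <- stats::rnorm(n_hh, 0, alpha_sd(config$baseline_cough))
  alpha_f <- stats::rnorm(n_hh, 0, alpha_sd(config$baseline_fever))
  alpha_r <- stats::rnorm(n_hh, 0, alpha_sd(config$baseline_diarrhea))

  # Controls per wave (wave 0 then wave 1); centered effects keep the
  # baselines interpretable as wave-1 prevalence.
  ln_cons0 <- stats::rnorm(n_hh, 9.59, 0.55)
  ln_cons1 <- ln_cons0 + stats::rnorm(n_hh, 0.32, 0.30)
  hh_size0 <- pmax(1L, stats::rpois(n_hh, 4.85) + 1L)
  hh_size1 <- pmax(1L, hh_size0 + sample(c(-2L, -1L, 0L), n_hh, TRUE,
                                         prob = c(0.25, 0.45, 0.30)))
  clean0 <- stats::rbinom(n_hh, 1, 0.25)
  clean1 <- pmax(clean0, stats::rbinom(n_hh, 1, 0.12))
  dung0 <- stats::rbinom(n_hh, 1, 0.40)
  dung1 <- pmin(dung0, stats::rbinom(n_hh, 1, 0.90))
  kitchen0 <- stats::rbinom(n_hh, 1, 0.598)
  kitchen1 <- stats::rbinom(n_hh, 1, 0.578)
  elec0 <- stats::rbinom(n_hh, 1, 0.764)
  elec1 <- pmax(elec0, stats::rbinom(n_hh, 1, 0.45))
  hours0 <- elec0 * pmin(24, pmax(0, stats::rnorm(n_hh, 15.2, 5)))
  hours1 <- elec1 * pmin(24, pmax(0, stats::rnorm(n_hh, 15.0, 5)))

  # Mover status is a household trait (the survey's 7-year recall window
  # spans the panel), reported in one of the two waves; the answer is
  # missing for a small household-level fraction.
  mig_p <- config$migration_fraction +
    config$migration_treatment_shift * (plants_hh > 0)
  mig_p <- pmin(pmax(mig_p, 0), 1)
  mover <- stats::rbinom(n_hh, 1, mig_p)
  report_in_wave1 <- stats::rbinom(n_hh, 1, 0.5) == 1
  moved0 <- as.integer(mover == 1 & !report_in_wave1)
  moved1 <- as.integer(mover == 1 & report_in_wave1)
  miss <- stats::rbinom(n_hh, 1, config$migration_missing_fraction) == 1
  moved0[miss] <- NA_integer_
  moved1[miss] <- NA_integer_

  control_term <- function(ln_cons, hh_size, clean, dung, kitchen, elec, hours) {
    config$coef_ln_cons * (ln_cons - 9.59) +
      config$coef_hh_size * (hh_size - 5.85) +
      config$coef_urban * (urban - config$urban_fraction) +
      config$coef_clean_fuel * (clean - 0.25) +
      config$coef_dung * (dung - 0.40) +
      config$coef_separate_kitchen * (kitchen - 0.598) +
      config$coef_electricity * (elec - 0.764) +
      config$coef_electricity_hours * (hours - 15.2)
  }
  ctrl0 <- control_term(ln_cons0, hh_size0, clean0, dung0, kitchen0, elec0, hours0)
  ctrl1 <- control_term(ln_cons1, hh_size1, clean1, dung1, kitchen1, elec1, hours1)

  if (!is.null(config$beta_capacity)) {
    dose <- capacity_hh / config$capacity_scale
    coal_term <- config$beta_capacity * dose +
      (config$beta_capacity2 %||% 0) * dose^2
  } else {
    coal_term <- config$beta_cough * plants_hh
  }
  noncoal_term <- config$beta_noncoal * noncoal_hh

  p_cough0 <- config$baseline_cough + alpha_c + ctrl0
  p_cough1 <- config$baseline_cough + alpha_c + ctrl1 +
    config$secular_trend_cough + coal_term + noncoal_term
  p_fever0 <- config$baseline_fever + alpha_f + ctrl0
  p_fever1 <- config$baseline_fever + alpha_f + ctrl1 +
    config$secular_trend_fever + config$beta_fever * plants_hh
  p_diar0 <- config$baseline_diarrhea + alpha_r + ctrl0
  p_diar1 <- config$baseline_diarrhea + alpha_r + ctrl1 +
    config$secular_trend_diarrhea + config$beta_diarrhea * plants_hh

  all_p <- c(p_cough0, p_cough1, p_fever0, p_fever1, p_diar0, p_diar1)
  clipped <- mean(all_p < 0 | all_p > 1)
  if (clipped > 0.01)
    abort_invalid_config(sprintf(
      "%.1f%% of implied outcome probabilities fall outside [0, 1]; reduce effect sizes or dispersion",
      100 * clipped))
  clip01 <- function(p) pmin(pmax(p, 0), 1)

  cough0 <- stats::rbinom(n_hh, 1, clip01(p_cough0))
  cough1 <- stats::rbinom(n_hh, 1, clip01(p_cough1))
  fever0 <- stats::rbinom(n_hh, 1, clip01(p_fever0))
  fever1 <- stats::rbinom(n_hh, 1, clip01(p_fever1))
  diar0 <- stats::rbinom(n_hh, 1, clip01(p_diar0))
  diar1 <- stats::rbinom(n_hh, 1, clip01(p_diar1))

  hid <- seq_len(n_hh)
  panel <- data.frame(
    household_id = c(hid, hid),
    psu_id = c(psu_of_hh, psu_of_hh),
    district_id = c(district_of_hh, district_of_hh),
    wave = rep(c(0L, 1L), each = n_hh),
    cough = c(cough0, cough1),
    fever = c(fever0, fever1),
    diarrhea = c(diar0, diar1),
    ln_cons_pc = c(ln_cons0, ln_cons1),
    hh_size = c(hh_size0, hh_size1),
    urban = c(urban, urban),
    clean_fuel = c(clean0, clean1),
    dung = c(dung0, dung1),
    separate_kitchen = c(kitchen0, kitchen1),
    has_electricity = c(elec0, elec1),
    electricity_hours = c(hours0, hours1),
    moved_within_7y = c(moved0, moved1)
  )
  list(panel = panel, exposures = exposures)
}

# District exposure table; called inside generate_panel() after set.seed.
generate_exposures <- function(config) {
  n_d <- config$n_districts
  n_t <- config$n_treated_districts
  treated <- sample.int(n_d, n_t)

  plants <- integer(n_d)
  counts <- as.integer(names(config$plant_count_weights))
  plants[treated] <- sample(counts, n_t, replace = TRUE,
                            prob = config$plant_count_weights)

  capacity <- numeric(n_d)
  mw_values <- as.numeric(names(config$capacity_mix))
  if (n_t > 0) {
    if (config$capacity_assignment == "quota") {
      alloc <- quota_counts(config$capacity_mix, n_t)
      caps <- rep(mw_values, alloc)
      capacity[treated] <- sample(caps, n_t)  # seeded shuffle over districts
    } else {
      capacity[treated] <- sample(mw_values, n_t, replace = TRUE,
                                  prob = config$capacity_mix)
    }
  }

  n_noncoal <- round(config$noncoal_district_fraction * n_d)
  noncoal <- integer(n_d)
  if (n_noncoal > 0) {
    nd <- sample.int(n_d, n_noncoal)
    noncoal[nd] <- sample(c(1L, 2L), n_noncoal, replace = TRUE,
                          prob = c(0.8, 0.2))
  }

  data.frame(
    district_id = seq_len(n_d),
    coal_plants_gained = plants,
    noncoal_plants_gained = noncoal,
    capacity_gained_mw = capacity
  )
}

#' Generate district-level census changes for pre-trend diagnostics
#'
#' Produces one row per district with changes over a pre-program decade in
#' five development indicators: infant mortality (deaths per 1,000), female
#' and total literacy, sanitation, and electrification (percentage points).
#' Under `null = TRUE` (the default) the changes are drawn independently of
#' coal-plant treatment, so parallel pre-trends hold by construction and the
#' pre-trend regression should find nothing. Setting `null = FALSE` injects a
#' linear confound (`confound_slope` per coal plant on `confound_outcome`) so
#' the power of the diagnostic can be tested.
#'
#' @param config A [synth_config()] object.
#' @param exposures District exposure table from [generate_panel()].
#' @param null Logical; generate under the parallel-trends null?
#' @param confound_outcome Column receiving the confound when `null = FALSE`.
#' @param confound_slope Injected change per coal plant gained.
#' @return A data.frame with columns `district_id`, `coal_plants_gained`,
#'   `d_imr`, `d_female_literacy`, `d_total_literacy`, `d_sanitation`,
#'   `d_electricity`.
#' @export
generate_census_changes <- function(config, exposures, null = TRUE,
                                    confound_outcome = "d_imr",
                                    confound_slope = 5) {
  stopifnot(inherits(config, "synth_config"))
  if (anyDuplicated(exposures$district_id))
    abort_integrity("duplicated district_id in exposure table")
  set.seed(child_seed(config$seed, 17L))
  n_d <- nrow(exposures)
  out <- data.frame(
    district_id = exposures$district_id,
    coal_plants_gained = exposures$coal_plants_gained,
    d_imr = stats::rnorm(n_d, -20.1, 50),
    d_female_literacy = stats::rnorm(n_d, 16.4, 8),
    d_total_literacy = stats::rnorm(n_d, 14.0, 7),
    d_sanitation = stats::rnorm(n_d, 13.4, 12),
    d_electricity = stats::rnorm(n_d, 14.6, 28)
  )
  if (!null) {
    if (!confound_outcome %in% names(out))
      abort_usage(sprintf("unknown confound outcome '%s'", confound_outcome))
    out[[confound_outcome]] <- out[[confound_outcome]] +
      confound_slope * out$coal_plants_gained
  }
  out
}
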