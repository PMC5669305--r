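#' Inputs for the discounted cost-of-illness calculator
#'
#' Assembles the inputs for [compute_cost()]. Defaults are the survey-based
#' values for an average Indian district and cough episode: Rs 550
#' out-of-pocket treatment cost and 4.09 missed days of work or school per
#' episode, a district population of 2.0 million, a 20-year plant life
#' discounted at 3.81% (the sovereign borrowing rate), market and
#' purchasing-power-parity conversions (Rs 60/USD market; Rs 14.0/USD PPP for
#' individual consumption; Rs 5.2/USD PPP for health), a conservative
#' workday valuation of Rs 159 (the lowest state workfare wage), and a
#' treatment effect of 0.0106 extra cough episodes per person-year per coal
#' plant (the un-rounded fixed-effects point estimate; the rounded 0.01 may
#' be substituted).
#'
#' @param cost_per_episode_inr Out-of-pocket rupees per cough episode.
#' @param days_per_episode Missed work/school days per episode.
#' @param district_population Persons exposed (average district population).
#' @param plant_life_years Assumed operating life of the plant in years.
#' @param discount_rate Annual discount rate (fraction).
#' @param beta_per_plant Extra cough probability per person-year per plant.
#' @param fx_market Market exchange rate, rupees per USD.
#' @param ppp_consumption PPP rate for individual consumption, Rs per USD.
#' @param ppp_health PPP rate for health, Rs per USD.
#' @param wage_inr_per_day Value of a missed day, rupees.
#' @param annuity_timing `"end"` (ordinary annuity; default) or `"begin"`
#'   (annuity due).
#' @return An object of class `"cost_inputs"`.
#' @export
cost_inputs <- function(cost_per_episode_inr = 550,
                        days_per_episode = 4.09,
                        district_population = 2.0e6,
                        plant_life_years = 20L,
                        discount_rate = 0.0381,
                        beta_per_plant = 0.0106,
                        fx_market = 60,
                        ppp_consumption = 14.0,
                        ppp_health = 5.2,
                        wage_inr_per_day = 159,
                        annuity_timing = c("end", "begin")) {
  annuity_timing <- match.arg(annuity_timing)
  inputs <- as.list(environment())
  pos <- c("cost_per_episode_inr", "days_per_episode", "district_population",
           "plant_life_years", "fx_market", "ppp_consumption", "ppp_health",
           "wage_inr_per_day")
  for (nm in pos) if (inputs[[nm]] <= 0)
    abort_usage(sprintf("%s must be strictly positive", nm))
  if (inputs$beta_per_plant < 0) abort_usage("beta_per_plant must be >= 0")
  if (inputs$discount_rate < 0) abort_usage("discount_rate must be >= 0")
  class(inputs) <- "cost_inputs"
  inputs
}

#' Annuity factor: discounted years of exposure per unit population
#'
#' Sum of per-year discount factors over the plant's life,
#' \deqn{\sum_{t=1}^{T} (1+r)^{-t}} for the default end-of-year (ordinary
#' annuity) convention, or the begin-of-year (annuity due) variant. At rate
#' zero the factor equals the plant life exactly.
#'
#' @param rate Annual discount rate (fraction, >= 0).
#' @param years Plant life in whole years (>= 1).
#' @param timing `"end"` (default) or `"begin"`.
#' @return Discounted years (scalar).
#' @export
#' @examples
#' annuity_factor(0.0381, 20)  # ~13.82 discounted years
annuity_factor <- function(rate, years, timing = c("end", "begin")) {
  timing <- match.arg(timing)
  if (years < 1) abort_usage("years must be at least 1")
  if (rate < 0) abort_usage("rate must be nonnegative")
  t <- seq_len(years)
  if (timing == "begin") t <- t - 1
  sum((1 + rate)^(-t))
}

#' Discounted externality cost of one coal plant through cough morbidity
#'
#' Converts the per-plant cough effect into a discounted money figure:
#' discounted person-years of exposure (population x annuity factor), extra
#' cough episodes (effect x person-years), out-of-pocket treatment costs
#' under three currency conversions, missed days and their conservative
#' wage valuation, and the headline total — out-of-pocket at the consumption
#' PPP rate plus the PPP-valued missed days — with a per-person-year cost.
#' Monetary fields are reported in millions of USD (rupee totals in millions
#' of rupees); full precision is retained (rounding is applied only when
#' printing).
#'
#' @param inputs A [cost_inputs()] object.
#' @return An object of class `"cost_breakdown"` with fields
#'   `annuity_factor`, `discounted_person_years`, `extra_episodes`,
#'   `oop_total_inr_m`, `oop_usd_market_m`, `oop_usd_ppp_consumption_m`,
#'   `oop_usd_ppp_health_m`, `days_lost_m`,
#'   `days_value_usd_ppp_consumption_m`, `total_usd_m`,
#'   `cost_per_person_year_usd`.
#' @export
#' @examples
#' compute_cost(cost_inputs())
compute_cost <- function(inputs = cost_inputs()) {
  stopifnot(inherits(inputs, "cost_inputs"))
  af <- annuity_factor(inputs$discount_rate, inputs$plant_life_years,
                       inputs$annuity_timing)
  dpy <- inputs$district_population * af
  episodes <- inputs$beta_per_plant * dpy
  oop_inr <- episodes * inputs$cost_per_episode_inr
  days <- episodes * inputs$days_per_episode
  days_value_usd <- days * inputs$wage_inr_per_day / inputs$ppp_consumption
  oop_ppp_cons <- oop_inr / inputs$ppp_consumption
  out <- list(
    annuity_factor = af,
    discounted_person_years = dpy,
    extra_episodes = episodes,
    oop_total_inr_m = oop_inr / 1e6,
    oop_usd_market_m = oop_inr / inputs$fx_market / 1e6,
    oop_usd_ppp_consumption_m = oop_ppp_cons / 1e6,
    oop_usd_ppp_health_m = oop_inr / inputs$ppp_health / 1e6,
    days_lost_m = days / 1e6,
    days_value_usd_ppp_consumption_m = days_value_usd / 1e6,
    total_usd_m = (oop_ppp_cons + days_value_usd) / 1e6,
    cost_per_person_year_usd = (oop_ppp_cons + days_value_usd) / dpy,
    inputs = inputs
  )
  class(out) <- "cost_breakdown"
  out
}

#' @export
print.cost_breakdown <- function(x, ...) {
  f <- function(v, d = 1) formatC(v, format = "f", digits = d)
  cat("Discounted marginal morbidity cost of one coal plant\n")
  cat(sprintf("  discounted person-years of exposure: %s m (annuity factor %s y)\n",
              f(x$discounted_person_years / 1e6), f(x$annuity_factor, 2)))
  cat(sprintf("  extra cough episodes:                %s m\n",
              f(x$extra_episodes / 1e6, 2)))
  cat("  out-of-pocket treatment cost:\n")
  cat(sprintf("    market exchange rate:              $%s m\n", f(x$oop_usd_market_m)))
  cat(sprintf("    PPP, individual consumption:       $%s m\n", f(x$oop_usd_ppp_consumption_m)))
  cat(sprintf("    PPP, health:                       $%s m\n", f(x$oop_usd_ppp_health_m)))
  cat(sprintf("  days of work/school missed:          %s m\n", f(x$days_lost_m)))
  cat(sprintf("  value of missed days (PPP cons.):    $%s m\n",
              f(x$days_value_usd_ppp_consumption_m)))
  cat(sprintf("  total (OOP at PPP cons. + days):     $%s m\n", f(x$total_usd_m)))
  cat(sprintf("  total per person-year of exposure:   $%s\n",
              f(x$cost_per_person_year_usd)))
  invisible(x)
}

#' Cost calculation from raw episode-cost samples
#'
#' Reduces survey vectors of per-episode out-of-pocket costs and missed days
#' by the chosen statistic (mean or median — cost data are typically heavily
#' right-skewed, so the median variant gives a robust lower figure), then
#' delegates to [compute_cost()].
#'
#' @param episode_costs_inr Numeric vector of per-episode rupee costs.
#' @param episode_days Numeric vector of per-episode missed days.
#' @param statistic `"mean"` or `"median"`.
#' @param ... Further arguments passed to [cost_inputs()].
#' @return A `"cost_breakdown"` object.
#' @export
cost_from_sample <- function(episode_costs_inr, episode_days,
                             statistic = c("mean", "median"), ...) {
  statistic <- match.arg(statistic)
  if (length(episode_costs_inr) == 0 || length(episode_days) == 0)
    abort_usage("episode cost and day vectors must be non-empty")
  red <- if (statistic == "mean") mean else stats::median
  compute_cost(cost_inputs(cost_per_episode_inr = red(episode_costs_inr),
                           days_per_episode = red(episode_days), ...))
}
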