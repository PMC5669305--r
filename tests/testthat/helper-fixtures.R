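# Small shared fixtures for the test suite.

small_config <- function(seed = 1L, ...) {
  defaults <- list(n_districts = 60, n_treated_districts = 8,
                   psus_per_district = 3, households_per_psu = 10,
                   seed = seed)
  do.call(synth_config, utils::modifyList(defaults, list(...)))
}

# Hand-built two-wave panel: n_hh households spread over districts/psus,
# with deterministic outcome values supplied by `y_fun(hh, wave)`.
toy_panel <- function(n_hh, district_of_hh, psu_of_hh, y_fun) {
  hh <- seq_len(n_hh)
  build_wave <- function(w) data.frame(
    household_id = hh, psu_id = psu_of_hh, district_id = district_of_hh,
    wave = w, cough = vapply(hh, y_fun, numeric(1), wave = w),
    fever = 0L, diarrhea = 0L, ln_cons_pc = 9.6, hh_size = 5L,
    urban = 0L, clean_fuel = 0L, dung = 0L, separate_kitchen = 0L,
    has_electricity = 1L, electricity_hours = 12,
    moved_within_7y = 0L)
  rbind(build_wave(0L), build_wave(1L))
}

toy_exposures <- function(n_districts, coal = NULL, noncoal = NULL,
                          capacity = NULL) {
  coal <- coal %||% rep(0L, n_districts)
  data.frame(district_id = seq_len(n_districts),
             coal_plants_gained = coal,
             noncoal_plants_gained = noncoal %||% rep(0L, n_districts),
             capacity_gained_mw = capacity %||% ((coal > 0) * 500))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
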