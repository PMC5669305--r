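# Table I/O with schema validation, plus the end-to-end runner.

panel_schema <- c("household_id", "psu_id", "district_id", "wave", "cough",
                  "fever", "diarrhea", "ln_cons_pc", "hh_size", "urban",
                  "clean_fuel", "dung", "separate_kitchen", "has_electricity",
                  "electricity_hours", "moved_within_7y")
exposure_schema <- c("district_id", "coal_plants_gained",
                     "noncoal_plants_gained", "capacity_gained_mw")
census_schema <- c("district_id", "coal_plants_gained", "d_imr",
                   "d_female_literacy", "d_total_literacy", "d_sanitation",
                   "d_electricity")

check_schema <- function(df, schema, what) {
  extra <- setdiff(names(df), schema)
  missing <- setdiff(schema, names(df))
  if (length(extra))
    abort_schema(sprintf("%s: unknown column(s): %s", what,
                         paste(extra, collapse = ", ")))
  if (length(missing))
    abort_schema(sprintf("%s: missing column(s): %s", what,
                         paste(missing, collapse = ", ")))
  df[, schema, drop = FALSE]
}

#' Read and write the pipeline's delimited tables
#'
#' The three tables (household x wave panel, district exposures, district
#' census changes) are stored as plain comma-separated text with fixed,
#' documented headers. Reading validates the schema and key integrity:
#' each household must appear exactly once per wave, each district once in
#' the district tables; violations are reported with the offending key.
#'
#' @param path File path.
#' @param panel,exposures,census_changes Tables to write.
#' @return The validated data.frame (readers); invisibly the path (writers).
#' @name table_io
NULL

#' @rdname table_io
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) abort_usage(sprintf("no such file: %s", path))
  df <- utils::read.csv(path)
  df <- check_schema(df, panel_schema, "panel")
  key <- paste(df$household_id, df$wave, sep = "/")
  if (anyDuplicated(key))
    abort_integrity(sprintf("duplicated household x wave key(s): %s",
                            paste(utils::head(unique(key[duplicated(key)]), 3),
                                  collapse = ", ")))
  waves_per_hh <- tabulate(factor(df$household_id))
  if (any(waves_per_hh != 2))
    abort_integrity("every household must appear in exactly two waves")
  psu_districts <- tapply(df$district_id, df$psu_id,
                          function(d) length(unique(d)))
  if (any(psu_districts > 1))
    abort_integrity("PSUs must nest within districts")
  df
}

#' @rdname table_io
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(check_schema(panel, panel_schema, "panel"), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_exposures <- function(path) {
  if (!file.exists(path)) abort_usage(sprintf("no such file: %s", path))
  df <- check_schema(utils::read.csv(path), exposure_schema, "exposures")
  if (anyDuplicated(df$district_id))
    abort_integrity("duplicated district_id in exposure table")
  bad <- xor(df$capacity_gained_mw > 0, df$coal_plants_gained > 0)
  if (any(bad))
    abort_integrity(sprintf(
      "capacity_gained_mw must be positive exactly when coal_plants_gained is (district %s)",
      df$district_id[which(bad)[1]]))
  df
}

#' @rdname table_io
#' @export
write_exposures <- function(exposures, path) {
  utils::write.csv(check_schema(exposures, exposure_schema, "exposures"),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_census <- function(path) {
  if (!file.exists(path)) abort_usage(sprintf("no such file: %s", path))
  df <- check_schema(utils::read.csv(path), census_schema, "census changes")
  if (anyDuplicated(df$district_id))
    abort_integrity("duplicated district_id in census table")
  if (anyNA(df)) abort_integrity("census table may not contain missing values")
  df
}

#' @rdname table_io
#' @export
write_census <- function(census_changes, path) {
  utils::write.csv(check_schema(census_changes, census_schema, "census changes"),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a fitted model as a machine-readable coefficient table
#'
#' @param fit A `"coal_fit"` object.
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_fit <- function(fit, path) {
  utils::write.csv(coef_table(fit), path, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline on a synthetic panel
#'
#' Executes the requested stages in order — `simulate` (generate the three
#' tables and write them), `estimate` (main fixed-effects regressions with
#' the three control blocks), `ri` (randomization inference), `diagnose`
#' (balance, pre-trends, falsification, migration, electrification), `dose`
#' (linear capped and quadratic full-sample dose-response plus capacity
#' coverage), `cost` (the discounted cost table) — writing one delimited
#' report per stage into `out_dir` together with a metadata file recording
#' the seed and configuration. All randomness derives from `config$seed`
#' (per-stage child seeds), so a rerun with the same configuration is
#' byte-identical.
#'
#' @param config A [synth_config()].
#' @param steps Character vector of stages (default: all, in order).
#' @param out_dir Output directory (created if needed).
#' @param ri_reps Randomization-inference replicates.
#' @return Invisibly, a named list of the in-memory stage results.
#' @export
run_pipeline <- function(config = synth_config(),
                         steps = c("simulate", "estimate", "ri", "diagnose",
                                   "dose", "cost"),
                         out_dir = tempfile("coalcough_run_"),
                         ri_reps = 1000L) {
  known <- c("simulate", "estimate", "ri", "diagnose", "dose", "cost")
  if (!all(steps %in% known))
    abort_usage(sprintf("unknown step(s): %s",
                        paste(setdiff(steps, known), collapse = ", ")))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()

  writeLines(c(sprintf("seed: %d", config$seed),
               sprintf("generated: %s", "coalcough run_pipeline"),
               sprintf("steps: %s", paste(steps, collapse = ", "))),
             file.path(out_dir, "run_metadata.txt"))

  tabs <- generate_panel(config)
  panel <- tabs$panel; exposures <- tabs$exposures

  run_step <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop(sprintf("pipeline step '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  for (step in steps) {
    results[[step]] <- switch(step,
      simulate = run_step("simulate", function() {
        write_panel(panel, file.path(out_dir, "panel.csv"))
        write_exposures(exposures, file.path(out_dir, "exposures.csv"))
        census <- generate_census_changes(config, exposures)
        write_census(census, file.path(out_dir, "census_changes.csv"))
        list(panel = panel, exposures = exposures, census = census)
      }),
      estimate = run_step("estimate", function() {
        fits <- list(
          fe_only = fit_lpm(panel, exposures, regression_spec(controls = "none")),
          demographic = fit_lpm(panel, exposures,
                                regression_spec(controls = "demographic")),
          full = fit_lpm(panel, exposures, regression_spec(controls = "full"))
        )
        tab <- do.call(rbind, lapply(names(fits), function(nm) {
          ct <- coef_table(fits[[nm]])
          cbind(model = nm, ct)
        }))
        utils::write.csv(tab, file.path(out_dir, "estimates.csv"),
                         row.names = FALSE)
        fits
      }),
      ri = run_step("ri", function() {
        ri <- randomization_inference(panel, exposures,
                                      R = ri_reps,
                                      seed = child_seed(config$seed, 23L))
        utils::write.csv(data.frame(permuted_beta = ri$permuted_betas),
                         file.path(out_dir, "ri_permuted_betas.csv"),
                         row.names = FALSE)
        writeLines(sprintf("observed_beta,%.10g\np_one_sided,%.10g",
                           ri$observed_beta, ri$p_one_sided),
                   file.path(out_dir, "ri_summary.csv"))
        ri
      }),
      diagnose = run_step("diagnose", function() {
        w0 <- panel[panel$wave == 0, ]
        treated <- exposures$coal_plants_gained[match(w0$district_id,
                                                      exposures$district_id)] > 0
        bal <- balance_test(w0, treated,
                            c("cough", "fever", "diarrhea", "ln_cons_pc",
                              "hh_size", "urban", "has_electricity"))
        utils::write.csv(bal, file.path(out_dir, "balance.csv"),
                         row.names = FALSE)
        census <- generate_census_changes(config, exposures)
        pre <- lapply(c("principal_component", "d_imr", "d_female_literacy",
                        "d_total_literacy", "d_sanitation", "d_electricity"),
                      function(oc) cbind(outcome = oc,
                                         coef_table(pretrend_regression(census, oc))))
        utils::write.csv(do.call(rbind, pre),
                         file.path(out_dir, "pretrends.csv"), row.names = FALSE)
        fals <- falsification_suite(panel, exposures)
        ft <- do.call(rbind, lapply(names(fals), function(nm)
          cbind(check = nm, coef_table(fals[[nm]]))))
        utils::write.csv(ft, file.path(out_dir, "falsification.csv"),
                         row.names = FALSE)
        mig <- lapply(c("drop_known_movers", "drop_movers_and_unknown"),
                      function(rule) {
          f <- fit_lpm(migration_exclusion(panel, rule), exposures,
                       regression_spec(controls = "none"))
          cbind(rule = rule, coef_table(f))
        })
        utils::write.csv(do.call(rbind, mig),
                         file.path(out_dir, "migration.csv"), row.names = FALSE)
        elec <- electrification_check(panel, exposures)
        et <- do.call(rbind, lapply(names(elec), function(nm)
          cbind(outcome = nm, coef_table(elec[[nm]]))))
        utils::write.csv(et, file.path(out_dir, "electrification.csv"),
                         row.names = FALSE)
        list(balance = bal, falsification = fals, electrification = elec)
      }),
      dose = run_step("dose", function() {
        lin <- fit_dose_response(panel, exposures,
                                 regression_spec(controls = "none"),
                                 form = "linear", capacity_cap_mw = 1000)
        quad <- fit_dose_response(panel, exposures,
                                  regression_spec(controls = "none"),
                                  form = "quadratic")
        cov <- capacity_coverage(exposures, panel, c(600, 1000))
        tab <- rbind(cbind(model = "linear_le_1000mw", coef_table(lin)),
                     cbind(model = "quadratic_full", coef_table(quad)))
        utils::write.csv(tab, file.path(out_dir, "dose_response.csv"),
                         row.names = FALSE)
        utils::write.csv(data.frame(threshold_mw = c(600, 1000),
                                    coverage = unname(cov)),
                         file.path(out_dir, "capacity_coverage.csv"),
                         row.names = FALSE)
        list(linear = lin, quadratic = quad, coverage = cov)
      }),
      cost = run_step("cost", function() {
        cb <- compute_cost(cost_inputs())
        flat <- unclass(cb)
        flat$inputs <- NULL
        utils::write.csv(data.frame(quantity = names(flat),
                                    value = unlist(flat)),
                         file.path(out_dir, "cost_breakdown.csv"),
                         row.names = FALSE)
        cb
      }))
  }
  invisible(results)
}
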