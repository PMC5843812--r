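# Run configuration and report assembly: the interface the analysis scripts
# drive. Configs are YAML; outputs are CSV tables plus a JSON run summary
# carrying inputs and seeds.

#' Read and validate a run configuration
#'
#' YAML schema (all keys optional, defaults shown by [default_run_config()]):
#' `A0_MBq`, `volumes_uL`, `horizon_s`, `n_histories`, `seed`,
#' `geometry: {height_mm, capacity_uL, half_angle_deg}`,
#' `chain_file` (a [write_chain()] file overriding the embedded data),
#' `output_dir`.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides named list applied on top of the file (e.g. parsed
#'   command-line flags).
#' @return a validated `run_config` list with a `geometry` object and
#'   `chain` attached.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  cfg <- utils::modifyList(cfg, overrides)
  stopifnot(cfg$A0_MBq >= 0, all(cfg$volumes_uL > 0), cfg$horizon_s > 0,
            cfg$n_histories >= 1)
  geo_args <- cfg$geometry
  cfg$geometry <- do.call(vial_geometry, geo_args)
  cfg$chain <- if (!is.null(cfg$chain_file)) {
    if (!file.exists(cfg$chain_file)) stop("chain file not found: ", cfg$chain_file)
    read_chain(cfg$chain_file)
  } else bi213_chain()
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

#' Default run configuration
#' @return list of defaults consumed by [read_run_config()].
#' @export
default_run_config <- function() {
  list(A0_MBq = 100,
       volumes_uL = c(10, 50, 100, 200, 400, 800),
       horizon_s = 7200,
       n_histories = 1e5,
       seed = 1L,
       geometry = list(height_mm = 20, capacity_uL = 1000),
       chain_file = NULL,
       output_dir = "results")
}

#' S-value comparison report
#'
#' Computes S-values over the configured volumes and tabulates them against
#' the published reference table; optionally writes CSVs and a JSON summary
#' to the configured output directory.
#'
#' @param config a `run_config`.
#' @param write write output files to `config$output_dir`.
#' @return list with `svalues` (computed table) and `comparison`.
#' @export
svalues_report <- function(config = read_run_config(), write = FALSE) {
  sv <- compute_svalues(config$chain, config$geometry, config$volumes_uL,
                        n = config$n_histories, seed = config$seed)
  cmp <- svalue_report(sv)
  if (write) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(sv, file.path(config$output_dir, "svalues_computed.csv"),
                     row.names = FALSE)
    utils::write.csv(cmp, file.path(config$output_dir, "svalues_comparison.csv"),
                     row.names = FALSE)
    write_run_summary(config, file.path(config$output_dir, "svalues_summary.json"),
                      list(max_abs_rel_dev = max(abs(cmp$rel_dev), na.rm = TRUE)))
  }
  list(svalues = sv, comparison = cmp)
}

#' Dose report for one fill volume
#'
#' Activities, dose-rate curve and cumulative dose at the configured horizon
#' for the configured initial activity, using either computed or reference
#' S-values.
#'
#' @param config a `run_config`.
#' @param volume_uL fill volume (default: the largest configured volume).
#' @param svalues an `svalue_table`; default the published reference table
#'   (instant); pass the result of [compute_svalues()] for the fully
#'   computed route.
#' @param write write CSV/JSON outputs.
#' @return list with `dose` (a `dose_result`), `initial_rate_mGy_s`,
#'   `cumulative_Gy` (analytic, at the horizon), `alpha_share_60min`.
#' @export
dose_report <- function(config = read_run_config(),
                        volume_uL = max(config$volumes_uL),
                        svalues = reference_svalues(), write = FALSE) {
  act <- chain_activities(config$chain, config$A0_MBq,
                          default_time_grid(config$horizon_s))
  dose <- dose_rate_curve(svalues, act, volume_uL)
  init <- initial_dose_rate(svalues, config$chain, config$A0_MBq, volume_uL)
  cum <- cumulative_dose(svalues, config$chain, config$A0_MBq, volume_uL,
                         config$horizon_s)
  share60 <- if (config$horizon_s >= 3600 && config$A0_MBq > 0)
    alpha_dose_share(dose, 3600) else NA_real_
  if (write) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(
      data.frame(time_s = dose$time_s, dose$rate_mGy_s,
                 cumulative_Gy = dose$cumulative_Gy),
      file.path(config$output_dir, "dose_curve.csv"), row.names = FALSE)
    write_run_summary(config, file.path(config$output_dir, "dose_summary.json"),
                      list(volume_uL = volume_uL,
                           initial_rate_mGy_s = as.list(init),
                           cumulative_Gy = cum, alpha_share_60min = share60))
  }
  list(dose = dose, initial_rate_mGy_s = init, cumulative_Gy = cum,
       alpha_share_60min = share60)
}

#' Labelling plan report
#'
#' For a recipe, activity and fill volume: calculated osmolarity, predicted
#' cumulative dose over the horizon, required ascorbic acid for that dose,
#' achievable specific activity, and the minimum peptide amount for a target
#' incorporation from a logistic curve (fitted or default truth-parameter).
#'
#' @param config a `run_config`.
#' @param recipe a `labelling_recipe` (default [optimized_recipe()] at the
#'   configured activity).
#' @param svalues S-value source for the dose prediction.
#' @param target_incorporation_pct target incorporation (%), default 99.
#' @param logistic list with `m50_nmol`, `slope_nmol`, `asymptote_pct`
#'   describing the incorporation curve (default: the generator defaults).
#' @param mole_ratio achieved metal:chelator ratio for the specific-activity
#'   line, default 0.6.
#' @param write write the JSON summary.
#' @return list of plan quantities.
#' @export
labelling_plan <- function(config = read_run_config(),
                           recipe = optimized_recipe(config$A0_MBq),
                           svalues = reference_svalues(),
                           target_incorporation_pct = 99,
                           logistic = list(m50_nmol = 2.4, slope_nmol = 0.25,
                                           asymptote_pct = 99),
                           mole_ratio = 0.6, write = FALSE) {
  vol <- recipe$total_volume_uL
  cum <- if (recipe$activity_MBq > 0)
    cumulative_dose(svalues, config$chain, recipe$activity_MBq, vol,
                    config$horizon_s) else 0
  asc <- required_ascorbic(cum, vol)
  sa_max <- max_specific_activity(config$chain$nuclides[[1]]$half_life_s)
  minpep <- min_peptide_for_incorporation(logistic, target_incorporation_pct)
  plan <- list(
    osmolarity_Osmol_L = osmolarity(recipe),
    predicted_dose_Gy = cum,
    horizon_s = config$horizon_s,
    required_ascorbic_mmol_L = asc$conc_mmol_L,
    ascorbic_extrapolated = asc$extrapolated,
    max_specific_activity_GBq_nmol = sa_max,
    achievable_sa_GBq_nmol = achievable_sa(sa_max, mole_ratio),
    min_peptide_nmol = minpep$peptide_nmol,
    min_peptide_at_asymptote = minpep$at_asymptote)
  if (write) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_run_summary(config, file.path(config$output_dir, "labelling_plan.json"),
                      plan)
  }
  plan
}

# JSON run summary with inputs and seed provenance.
write_run_summary <- function(config, path, results) {
  jsonlite::write_json(
    list(inputs = list(A0_MBq = config$A0_MBq, volumes_uL = config$volumes_uL,
                       horizon_s = config$horizon_s,
                       n_histories = config$n_histories, seed = config$seed,
                       geometry = unclass(config$geometry)[
                         c("height_mm", "capacity_uL", "half_angle_deg")]),
         results = results,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
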