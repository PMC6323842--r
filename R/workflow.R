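#' Experiment run configuration
#'
#' A fully serializable description of a simulation experiment: the scenario
#' table, the plan and phantom parameters, sampling intervals and seeds.
#' Re-running an archived configuration reproduces all outputs bit-
#' identically.
#'
#' @param scenarios scenario data.frame (default [table1_scenarios()]).
#' @param replicates traces per scenario.
#' @param base_seed integer base seed for all derived seeds.
#' @param prescription_gy,n_fractions,isodose_level,core_depth_mm,penumbra_sigma_mm
#'   plan parameters (see [plan_spec()]).
#' @param grid_shape,voxel_mm phantom parameters (see [phantom_grid()]).
#' @param diameter_cm target sphere diameter (cm).
#' @param duration_s,sample_interval_s trace generation parameters.
#' @param true_interval_s resampling interval of the true dose (s).
#' @param noise_sd_mm,sample_rate_hz,cutoff_hz patient-like trace settings.
#' @param coverage robust-strategy pdf coverage.
#' @param output_dir directory for command outputs.
#' @return an object of class `run_config`.
#' @export
run_config <- function(scenarios = table1_scenarios(), replicates = 10,
                       base_seed = 20190108L,
                       prescription_gy = 60, n_fractions = 5,
                       isodose_level = 0.80, core_depth_mm = 5,
                       penumbra_sigma_mm = 3,
                       grid_shape = c(120L, 120L, 120L), voxel_mm = 1,
                       diameter_cm = 3,
                       duration_s = 100, sample_interval_s = 0.02,
                       true_interval_s = 0.4,
                       noise_sd_mm = 0.5, sample_rate_hz = 30, cutoff_hz = 1,
                       coverage = 0.8,
                       output_dir = "dose4d-run") {
  structure(
    list(scenarios = scenarios, replicates = as.integer(replicates),
         base_seed = as.integer(base_seed),
         prescription_gy = prescription_gy, n_fractions = n_fractions,
         isodose_level = isodose_level, core_depth_mm = core_depth_mm,
         penumbra_sigma_mm = penumbra_sigma_mm,
         grid_shape = as.integer(grid_shape), voxel_mm = voxel_mm,
         diameter_cm = diameter_cm,
         duration_s = duration_s, sample_interval_s = sample_interval_s,
         true_interval_s = true_interval_s,
         noise_sd_mm = noise_sd_mm, sample_rate_hz = sample_rate_hz,
         cutoff_hz = cutoff_hz, coverage = coverage,
         output_dir = output_dir),
    class = "run_config"
  )
}

config_plan_spec <- function(config) {
  plan_spec(config$prescription_gy, config$n_fractions,
            config$isodose_level, config$core_depth_mm,
            config$penumbra_sigma_mm)
}

config_grid <- function(config) {
  phantom_grid(config$grid_shape, config$voxel_mm)
}

#' Read / write a run configuration as YAML
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$scenarios <- as.list(as.data.frame(config$scenarios))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$scenarios <- as.data.frame(x$scenarios)
  do.call(run_config, x[names(x) %in% names(formals(run_config))])
}

# md5 fingerprint of a config, via its canonical YAML serialization
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_run_config(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Simulate and archive the scenario trace bank
#'
#' Writes one CSV per (scenario, replicate) trace plus a JSON manifest
#' mapping each filename to its scenario parameters, replicate and seed,
#' alongside the config fingerprint.
#'
#' @param config a [run_config()].
#' @return invisibly, the manifest data.frame (with a `file` column).
#' @export
cmd_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir <- file.path(config$output_dir, "traces")
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create output directory: ", dir)
  }
  bank <- generate_scenario_bank(config$scenarios, config$replicates,
                                 config$base_seed, config$duration_s,
                                 config$sample_interval_s)
  manifest <- attr(bank, "manifest")
  manifest$file <- sprintf("trace_row%02d_rep%02d.csv", manifest$row,
                           manifest$replicate)
  for (i in seq_along(bank)) {
    write_trace_csv(bank[[i]], file.path(dir, manifest$file[i]))
  }
  meta <- list(config_md5 = config_hash(config),
               base_seed = config$base_seed,
               traces = manifest)
  jsonlite::write_json(meta, file.path(config$output_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Run the end-to-end discrepancy evaluation
#'
#' Re-simulates the scenario bank from the config seeds, runs the phantom /
#' dose / accumulation / evaluation pipeline, and writes the sweep summary
#' CSV, the linear trend fits and a JSON run report carrying the config
#' fingerprint and every seed used.
#'
#' @param config a [run_config()].
#' @return invisibly, the [run_sweep()] result.
#' @export
cmd_evaluate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(config$output_dir) &&
      !dir.create(config$output_dir, recursive = TRUE)) {
    stop("cannot create output directory: ", config$output_dir)
  }
  bank <- generate_scenario_bank(config$scenarios, config$replicates,
                                 config$base_seed, config$duration_s,
                                 config$sample_interval_s)
  res <- run_sweep(bank, config_plan_spec(config), config_grid(config),
                   diameter_cm = config$diameter_cm,
                   true_interval_s = config$true_interval_s)
  write.csv(res$summary, file.path(config$output_dir, "sweep_summary.csv"),
            row.names = FALSE)

  trends <- list()
  amp <- res$summary[res$summary$excursion_cv == 0.25 &
                       res$summary$mean_period_s == 4 &
                       res$summary$period_cv == 0.2, ]
  if (nrow(amp) >= 2) {
    trends$amplitude <- unclass(fit_trend(amp$mean_excursion_mm,
                                          amp$delta_d99, "mean_amplitude_mm"))
  }
  cv <- res$summary[res$summary$mean_excursion_mm == 15 &
                      res$summary$mean_period_s == 4 &
                      res$summary$period_cv == 0.2, ]
  if (nrow(cv) >= 2) {
    trends$amplitude_cv <- unclass(fit_trend(cv$excursion_cv, cv$delta_d99,
                                             "amplitude_cv"))
  }
  report <- list(
    config_md5 = config_hash(config),
    base_seed = config$base_seed,
    seeds = attr(bank, "manifest")$seed,
    trends = trends
  )
  jsonlite::write_json(report, file.path(config$output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' Run the robust-strategy comparison for synthetic patients
#'
#' For each requested patient of [table3_patients()] (synthetically
#' emulated), runs [run_patient_robust()] and writes a JSON report with the
#' coverage intervals, position sets, per-fraction doses and paired-test
#' results.
#'
#' @param config a [run_config()].
#' @param patients patient ids (subset of 1:3).
#' @return invisibly, a named list of [run_patient_robust()] results.
#' @export
cmd_robust <- function(config, patients = 1:3) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(config$output_dir) &&
      !dir.create(config$output_dir, recursive = TRUE)) {
    stop("cannot create output directory: ", config$output_dir)
  }
  tab <- table3_patients()
  out <- list()
  for (p in patients) {
    rows <- tab[tab$patient == p, ]
    if (nrow(rows) == 0) stop("unknown patient id: ", p)
    res <- run_patient_robust(
      rows, config_plan_spec(config), config_grid(config),
      diameter_cm = config$diameter_cm,
      base_seed = config$base_seed + 100L * p,
      noise_sd_mm = config$noise_sd_mm,
      sample_rate_hz = config$sample_rate_hz,
      cutoff_hz = config$cutoff_hz,
      coverage = config$coverage,
      true_interval_s = config$true_interval_s
    )
    out[[paste0("patient", p)]] <- res
  }
  report <- list(
    config_md5 = config_hash(config),
    base_seed = config$base_seed,
    patients = lapply(out, function(r) {
      list(traditional_positions = r$traditional_positions,
           coverage_interval = as.list(r$coverage_interval),
           extended_positions = r$extended_positions,
           fractions = r$fractions,
           mean_difference = r$comparison$mean_difference,
           p_paired_t = r$comparison$p_paired_t,
           p_wilcoxon = r$comparison$p_wilcoxon)
    })
  )
  jsonlite::write_json(report, file.path(config$output_dir, "robust_report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(out)
}
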