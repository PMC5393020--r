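#' Default run configuration
#'
#' Flat list of every knob of the end-to-end pipeline, with units in the
#' key names. Serializable to a human-editable YAML file via
#' [write_run_config()].
#'
#' @param case_table Path to the case-table CSV (default: the bundled
#'   ten-case cohort).
#' @param output_dir Output directory (`NULL`: no files written).
#' @param ... Overrides of individual keys.
#' @return Named list of configuration values.
#' @export
run_config <- function(case_table = NULL, output_dir = NULL, ...) {
  cfg <- list(
    case_table = case_table %||%
      system.file("extdata", "bundled_cases.csv", package = "scolisim"),
    output_dir = output_dir,
    base_seed = 1,
    patterns = 1:5,
    convexity_mt = "right",
    rod_contour_convex_deg = 25,
    rod_contour_concave_deg = 35,
    rod_lumbar_contour_deg = 30,
    rod_diameter_mm = 5.5,
    rod_modulus_N_mm2 = 230000,
    translation_steps = 20,
    bend_moment_t1_Nmm = 5000,
    bend_moment_distributed_Nmm = 300,
    solver_ftol_N = 0.5,
    solver_ttol_Nmm = 50,
    verbose = TRUE
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a run configuration as YAML
#' @param config A [run_config()] list.
#' @param path File path.
#' @return `path` (write) or the configuration list (read).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full simulation pipeline on a cohort
#'
#' For every case: generate the synthetic spine from its clinical
#' indices, calibrate the patient-specific stiffness against the
#' side-bending Cobb angles, apply the surgical release over the
#' instrumented levels, and simulate simultaneous two-rod segmental
#' translation under each requested screw pattern; then pool the cohort
#' into a [summarize_cohort()] summary with pattern comparisons.
#' Per-case failures are isolated (remaining cases continue) and
#' recorded in the manifest.
#'
#' @param config A [run_config()] list.
#' @param cases Optional subset: integer indices into the case table.
#' @param params Calibrated `stiffness_params`.
#' @return A `cohort_summary` with the per-case run list attached as
#'   attribute `"runs"` and the manifest as attribute `"manifest"`.
#' @export
run_pipeline <- function(config = run_config(), cases = NULL,
                         params = calibrated_params()) {
  all_cases <- read_case_table(config$case_table)
  if (!is.null(cases)) all_cases <- all_cases[cases]
  say <- function(...) if (isTRUE(config$verbose)) message(...)
  runs <- list()
  failures <- list()
  for (ci in all_cases) {
    t0 <- Sys.time()
    run <- tryCatch({
      g <- generate_spine(ci, seed = case_seed(ci, config$base_seed))
      pc <- calibrate_patient(g, ci, params,
                              load = bending_load(
                                config$bend_moment_t1_Nmm,
                                config$bend_moment_distributed_Nmm))
      fused <- level_range(ci$uiv, ci$liv)
      m <- calibrated_model(g, ci, pc, params)
      m <- apply_surgical_release(m, fused)
      convex <- config$convexity_mt
      concave <- if (convex == "right") "left" else "right"
      rods <- list()
      rods[[convex]] <- contour_rod(convex, g, fused,
                                    config$rod_contour_convex_deg,
                                    config$rod_lumbar_contour_deg,
                                    diameter = config$rod_diameter_mm,
                                    E = config$rod_modulus_N_mm2)
      rods[[concave]] <- contour_rod(concave, g, fused,
                                     config$rod_contour_concave_deg,
                                     config$rod_lumbar_contour_deg,
                                     diameter = config$rod_diameter_mm,
                                     E = config$rod_modulus_N_mm2)
      results <- list()
      for (k in config$patterns) {
        pat <- make_pattern(fused, ci$mt_apex, convex, k)
        res <- simulate_segmental_translation(
          m, g, pat, rods, nsteps = config$translation_steps,
          ftol = config$solver_ftol_N, ttol = config$solver_ttol_Nmm)
        results[[as.character(k)]] <- res
      }
      say(sprintf("case %s: %d pattern(s) simulated (%.1f s)", ci$case_id,
                  length(results), as.numeric(Sys.time() - t0, "secs")))
      list(indices = ci, geometry = g, calibration = pc, results = results)
    }, error = function(e) {
      failures[[ci$case_id]] <<- conditionMessage(e)
      say(sprintf("case %s FAILED: %s", ci$case_id, conditionMessage(e)))
      NULL
    })
    if (!is.null(run)) runs[[ci$case_id]] <- run
  }
  summary <- summarize_cohort(runs)
  manifest <- list(
    package_version = as.character(utils::packageVersion("scolisim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    config = config[!vapply(config, is.null, logical(1))],
    n_cases = length(runs),
    failures = failures,
    convergence = lapply(runs, function(run)
      vapply(run$results, function(r) r$converged, logical(1)))
  )
  attr(summary, "runs") <- runs
  attr(summary, "manifest") <- manifest
  if (!is.null(config$output_dir)) {
    write_cohort_outputs(summary, config$output_dir, manifest)
  }
  summary
}

# CSV / JSON artifacts of a cohort run
write_cohort_outputs <- function(summary, dir, manifest = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(summary$indices, file.path(dir, "indices.csv"),
                   row.names = FALSE)
  utils::write.csv(summary$forces, file.path(dir, "forces.csv"),
                   row.names = FALSE)
  utils::write.csv(summary$pooled_forces, file.path(dir, "force_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(compare_patterns(summary),
                   file.path(dir, "comparisons.csv"), row.names = FALSE)
  if (!is.null(summary$deviations)) {
    utils::write.csv(summary$deviations, file.path(dir, "deviations.csv"),
                     row.names = FALSE)
  }
  if (!is.null(manifest)) {
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}
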