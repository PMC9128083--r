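# End-to-end pipeline driver: simulate (optional) -> process -> CHIP-call
# -> trajectories -> associate -> validate.

# gather per-timepoint observations of each driver variant so that
# undetected timepoints (alt below detection) enter trajectories as zeros
collect_driver_observations <- function(drivers, observations) {
  key <- unique(paste(drivers$subject_id, drivers$variant_id))
  obs_key <- paste(observations$subject_id, observations$variant_id)
  out <- observations[obs_key %in% key, , drop = FALSE]
  ann <- drivers[!duplicated(drivers$variant_id),
                 c("variant_id", "gene", "protein_change")]
  out <- merge(out, ann, by = "variant_id")
  out[order(out$subject_id, out$variant_id, out$timepoint), , drop = FALSE]
}

#' Run the full CHIP analysis pipeline on a simulated cohort
#'
#' Simulates a cohort, processes observations through the caller and
#' filters, annotates CHIP drivers against the whitelist, summarizes CHIP
#' status and prevalence, fits clone trajectories with dominant-clone,
#' competition and gene-group summaries, runs the association models, and
#' estimates the sequencing error rate from the invariant background
#' sites. All outputs are written as TSV under `out_dir` together with a
#' YAML run manifest (seed, parameters, per-stage record counts).
#' Reruns with the same configurations are output-identical.
#'
#' @param sim_config a [cohort_config()].
#' @param config a [pipeline_config()].
#' @param whitelist a [read_whitelist()] object.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return (invisibly) a list with all stage results: `sim`, `calls`,
#'   `drivers`, `status`, `prevalence`, `trajectories`, `fits`,
#'   `dominant`, `competition`, `error_rate`, `associations`.
#' @export
run_chip_pipeline <- function(sim_config = cohort_config(),
                              config = pipeline_config(),
                              whitelist = read_whitelist(),
                              out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) stop("config must be a pipeline_config")
  sim <- simulate_cohort(sim_config)
  if (is.null(sim$observations) || nrow(sim$observations) == 0)
    stop("stage simulate: cohort produced no observations")

  calls <- process_observations(
    sim$observations, error_rate = config$error_rate, alpha = config$alpha,
    min_depth = config$min_depth, min_alt = config$min_alt,
    min_vaf = config$min_vaf, artifact_prop = config$artifact_prop,
    artifact_window = config$artifact_window
  )

  drivers <- annotate_drivers(calls, sim$annotations, whitelist)
  status <- chip_status(drivers, sim$manifest, config$chip_vaf, config$large_vaf)
  prevalence <- prevalence_by_age(status, sim$manifest, config$age_breaks)

  driver_obs <- collect_driver_observations(drivers, sim$observations)
  traj <- assemble_trajectories(
    driver_obs, sim$manifest,
    min_timepoints = config$traj_min_timepoints,
    min_peak_vaf = config$traj_min_peak_vaf,
    min_depth = config$traj_min_depth, min_alt = config$traj_min_alt
  )
  traj <- exclude_high_start(traj, config$max_start_vaf)
  fits <- fit_trajectories(traj, vaf_floor = config$vaf_floor,
                           p_threshold = config$p_threshold)
  dominant <- select_dominant(traj)
  competition <- competition_report(fits, traj, config$chip_vaf)

  # invariant background sites -> pooled error rate
  bg <- sim$observations[sim$observations$site_class == "background", ]
  error_est <- if (nrow(bg) > 0)
    estimate_error_rate(bg$alt_count, bg$depth) else NULL

  # association stages (skipped, with a note, when the cohort is too small)
  subj_cov <- sim$manifest[!duplicated(sim$manifest$subject_id),
                           c("subject_id", "age", "race", "smoking", "bmi",
                             "first_visit_year")]
  first_tp <- stats::aggregate(timepoint ~ subject_id, sim$manifest, min)
  first_status <- merge(first_tp, status, by = c("subject_id", "timepoint"))
  cs_data <- merge(subj_cov, first_status, by = "subject_id")
  cs_data$large_clone <- cs_data$n_clones_10pct >= 1L
  associations <- list()
  associations$cross_sectional <- tryCatch(
    cross_sectional_model(cs_data, "chip_prevalence"),
    error = function(e) paste("skipped:", conditionMessage(e)))
  growth_data <- merge(dominant, subj_cov, by = "subject_id")
  associations$growth <- tryCatch(
    longitudinal_growth_model(growth_data),
    error = function(e) paste("skipped:", conditionMessage(e)))

  res <- list(sim = sim, calls = calls, drivers = drivers, status = status,
              prevalence = prevalence, trajectories = traj, fits = fits,
              dominant = dominant, competition = competition,
              error_rate = error_est, associations = associations)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(df, name)
      utils::write.table(df, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    wt(sim$manifest, "manifest.tsv")
    wt(calls, "calls.tsv")
    wt(drivers, "drivers.tsv")
    wt(status, "chip_status.tsv")
    wt(prevalence, "prevalence.tsv")
    wt(traj, "trajectory_observations.tsv")
    wt(fits, "trajectories.tsv")
    wt(dominant, "dominant_clones.tsv")
    wt(competition, "competition.tsv")
    if (is.data.frame(associations$cross_sectional))
      wt(associations$cross_sectional, "association_cross_sectional.tsv")
    if (is.data.frame(associations$growth))
      wt(associations$growth, "association_growth.tsv")
    manifest <- list(
      seed = sim_config$seed,
      parameters = unclass(config),
      counts = list(
        samples = nrow(sim$manifest),
        subjects = length(unique(sim$manifest$subject_id)),
        observations = nrow(sim$observations),
        pass_calls = sum(calls$pass),
        drivers = nrow(drivers),
        trackable_mutations = nrow(fits),
        growing = sum(fits$label == "growing", na.rm = TRUE),
        shrinking = sum(fits$label == "shrinking", na.rm = TRUE),
        static = sum(fits$label == "static", na.rm = TRUE)
      ),
      error_rate_estimate = if (!is.null(error_est)) error_est$rate else NA
    )
    yaml::write_yaml(manifest, file.path(out_dir, "run_manifest.yaml"))
  }
  invisible(res)
}
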