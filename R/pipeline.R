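#' Run the full analysis pipeline on simulated trials
#'
#' End-to-end composition of the analysis stages: for each baseline force
#' (default 25/50/75/100 mN), simulate a trial with the virtual larva, segment
#' the force trace into waves, match them to the behaviour annotations, group
#' bouts, compute per-wave metrics and rescaled series, the direction-effect
#' fractions, and the behaviour-force coupling statistics. All outputs carry
#' seed and configuration provenance and are byte-reproducible from
#' `config + seed`.
#'
#' @param config A named list (or path to a YAML file, see [read_config()])
#'   with optional entries: `seed` (default 1), `baseline_forces` (default
#'   `c(25, 50, 75, 100)`), `k` (elastic coefficient, mN/mm; required — no
#'   measured default exists; the virtual larva's default 60 is used only if
#'   `use_default_k = TRUE`), `trials_per_baseline` (default 1), `peak_params`
#'   (list of window_s/min_prominence/min_distance_s), `out_dir` (optional:
#'   write CSV/JSON outputs there).
#' @return A list of class `analysis_report`: `waves`, `metrics`, `rescaled`,
#'   `fractions`, `coupling`, `config`.
#' @export
run_full_analysis <- function(config = list()) {
  if (is.character(config)) config <- read_config(config)
  if (is.null(config$k)) {
    if (isTRUE(config$use_default_k)) config$k <- 60
    else stop("run_full_analysis: config must provide the elastic coefficient 'k' (mN/mm)")
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  baselines <- if (is.null(config$baseline_forces)) c(25, 50, 75, 100) else config$baseline_forces
  n_trials <- if (is.null(config$trials_per_baseline)) 1L else config$trials_per_baseline
  pp <- if (is.null(config$peak_params)) peak_params() else
    do.call(peak_params, config$peak_params)
  params <- if (is.null(config$larva)) larva_params(elastic_coefficient_k = config$k)
            else do.call(larva_params, c(config$larva, list()))

  waves_all <- list(); metrics_all <- list(); rescaled_all <- list()
  coupling_all <- list(); row <- 0L
  for (b in baselines) {
    for (j in seq_len(n_trials)) {
      row <- row + 1L
      trial_seed <- seed + 1000L * (row - 1L)
      geom <- cleft_geometry(baseline_force = b)
      trial <- simulate_trial(params, geom, seed = trial_seed)
      wv <- segment_waves(trial$force_trace, pp)
      wv <- match_to_behavior(wv, trial$behavior)
      wv <- group_bouts(wv)
      mt <- metrics_by_bout(wv, k = config$k)
      prov <- data.frame(baseline_mN = b, trial = j, seed = trial_seed)
      waves_all[[row]] <- cbind(prov[rep(1L, nrow(wv)), , drop = FALSE], wv)
      metrics_all[[row]] <- cbind(prov[rep(1L, nrow(mt)), , drop = FALSE], mt)
      rs <- do.call(rbind, lapply(split(mt, mt$bout_id), function(d) {
        if (!nrow(d)) return(NULL)
        data.frame(baseline_mN = b, trial = j, seed = trial_seed,
                   bout_id = d$bout_id, direction = d$direction,
                   wave_index = d$wave_index,
                   amplitude_rescaled = as.numeric(rescale_series(d$amplitude)),
                   duration_rescaled = as.numeric(rescale_series(d$duration)),
                   work_rescaled = as.numeric(rescale_series(d$work)))
      }))
      rescaled_all[[row]] <- rs
      cp <- coupling_analysis(trial$force_trace, trial$behavior)
      coupling_all[[row]] <- data.frame(
        baseline_mN = b, trial = j, seed = trial_seed,
        r_pb_forward = cp$forward$r_pb, r_pb_backward = cp$backward$r_pb,
        n_samples = cp$n_samples)
    }
  }
  waves <- do.call(rbind, waves_all)
  metrics <- do.call(rbind, metrics_all)
  rescaled <- do.call(rbind, rescaled_all)
  coupling <- do.call(rbind, coupling_all)
  fractions <- direction_effect_fractions(metrics)
  config$seed <- seed
  report <- structure(list(waves = waves, metrics = metrics,
                           rescaled = rescaled, fractions = fractions,
                           coupling = coupling, config = config),
                      class = "analysis_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write an analysis report bundle
#'
#' @param report An `analysis_report`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wcsv <- function(df, name) {
    utils::write.csv(format(df, digits = 10, trim = TRUE),
                     file.path(dir, name), row.names = FALSE, quote = FALSE)
  }
  wcsv(report$waves, "waves.csv")
  wcsv(report$metrics, "metrics.csv")
  if (!is.null(report$rescaled) && nrow(report$rescaled))
    wcsv(report$rescaled, "rescaled.csv")
  wcsv(report$coupling, "coupling.csv")
  cfg <- report$config
  cfg$out_dir <- NULL  # path provenance would break byte-reproducibility
  jsonlite::write_json(list(fractions = report$fractions, config = cfg),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Generate the canonical synthetic fixture suite
#'
#' Writes the seeded set of synthetic trials used for validation: a noiseless
#' trial, a noisy trial, a short-delay (overlapping-wave) trial, an
#' early-termination trial (large backward decrements under a low baseline),
#' and one trial per baseline force (25/50/75/100 mN), plus a JSON manifest.
#'
#' @param seed Top-level seed.
#' @param dir Output directory.
#' @return Invisibly, the manifest (data.frame of trial name, seed, files).
#' @export
make_fixture_suite <- function(seed = 1, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  specs <- list(
    noiseless = list(params = larva_params(noise_sd = 0), baseline = 25),
    noisy = list(params = larva_params(noise_sd = 0.5), baseline = 25),
    overlapping = list(params = larva_params(noise_sd = 0,
                                             inter_wave_delay_mean = 2,
                                             inter_wave_delay_sd = 0.3),
                       baseline = 25),
    early_termination = list(
      params = larva_params(noise_sd = 0, backward_increment_mean = -30,
                            backward_increment_sd = 1,
                            policy = locomotion_policy(p_forward = 0, p_pause = 0)),
      baseline = 25),
    baseline_25 = list(params = larva_params(), baseline = 25),
    baseline_50 = list(params = larva_params(), baseline = 50),
    baseline_75 = list(params = larva_params(), baseline = 75),
    baseline_100 = list(params = larva_params(), baseline = 100)
  )
  manifest <- list()
  for (i in seq_along(specs)) {
    nm <- names(specs)[i]
    s <- specs[[i]]
    trial_seed <- as.integer(seed) + i
    trial <- simulate_trial(s$params, cleft_geometry(baseline_force = s$baseline),
                            seed = trial_seed)
    paths <- write_trial(trial, dir, stem = nm)
    manifest[[i]] <- data.frame(name = nm, seed = trial_seed,
                                baseline_mN = s$baseline,
                                n_truth_waves = nrow(trial$truth),
                                terminated_early = trial$terminated_early,
                                trace = basename(paths[["trace"]]))
  }
  manifest <- do.call(rbind, manifest)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
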