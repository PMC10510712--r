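#' Pipeline run configuration
#'
#' Bundles the per-stage configurations of a full analysis run
#' (simulate, render, detect, track, profile, classify, extract events,
#' fit). The acquisition mode fixes the defaults of every stage; any
#' field can be overridden.
#'
#' @param mode acquisition mode, see [simulation_config()].
#' @param sim a [simulation_config()]; default one built from `mode` and
#'   `seed`.
#' @param particle_size_nm nominal particle size, sets the linking cap.
#' @param expected_diameter_nm spot diameter for detection; default
#'   4x the particle-channel PSF sigma.
#' @param min_quality detection quality threshold (counts); default
#'   scales with the photon budget.
#' @param background_radius_px Gaussian background-subtraction radius in
#'   pixels, or NULL to skip (default 5 for 40 nm particles, NULL
#'   otherwise, since dye leakage is a small-particle problem).
#' @param membrane_sampling `"per_frame"` or `"before_after"`, see
#'   [classify_tracks()].
#' @param bin_width_s histogram bin width for the exponential fits;
#'   default the frame interval (event times are frame-quantized).
#' @param cutoff_s short-event cutoff for summaries (default 60 s).
#' @param seed seed for the run (overrides `sim$seed`).
#' @return list of class `run_config`.
#' @export
run_config <- function(mode = c("confocal2d", "confocal3d", "sted"),
                       sim = NULL, particle_size_nm = 100,
                       expected_diameter_nm = NULL, min_quality = NULL,
                       background_radius_px = if (particle_size_nm == 40) 5 else NULL,
                       membrane_sampling = "per_frame",
                       bin_width_s = NULL, cutoff_s = 60, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(sim)) sim <- simulation_config(mode = mode, seed = seed)
  else { sim$seed <- as.integer(seed); validate_simulation_config(sim) }
  structure(list(
    mode = mode, sim = sim,
    tracker = tracker_config(particle_size_nm),
    classifier = classifier_config(sim$pitch_nm),
    expected_diameter_nm = expected_diameter_nm %||%
      (4 * sim$psf_sigma_particle_nm),
    min_quality = min_quality %||%
      (0.02 * sim$particle_photons * sim$photon_scale *
         (sim$pitch_nm / (sim$psf_sigma_particle_nm + sim$pitch_nm))),
    background_radius_px = background_radius_px,
    membrane_sampling = membrane_sampling,
    bin_width_s = bin_width_s %||% sim$dt_s,
    cutoff_s = cutoff_s, seed = as.integer(seed)),
    class = "run_config")
}

#' Run the full residence-time pipeline on a simulated movie
#'
#' Simulates kinetics, renders the movie, detects and links particles,
#' classifies per-frame states against the membrane, extracts residence
#' events, and fits characteristic times. All intermediate tables are
#' written to `out_dir` as CSV/JSON together with a manifest (seed,
#' config hash, per-stage record counts); rerunning with the same
#' configuration and seed reproduces every output bit-exactly.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory, or NULL to skip writing.
#' @param write_movie also write the rendered movie as TIFF (default
#'   FALSE; the movie can be large).
#' @return list of class `pipeline_run` with elements `log`, `stack`,
#'   `detections`, `tracks`, `states`, `events`, `summary`,
#'   `fit_desorption`, `fit_internalization` (either fit NULL when there
#'   are too few events), and `manifest`.
#' @export
run_pipeline <- function(cfg, out_dir = NULL, write_movie = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  sim <- cfg$sim
  log <- simulate_kinetics(sim)
  stack <- render_movie(log, sim)
  detections <- detect_movie(stack, cfg$expected_diameter_nm,
                             min_quality = cfg$min_quality,
                             background_radius_px = cfg$background_radius_px)
  linked_input <- if (sim$n_z > 1L)
    merge_z_detections(detections, cfg$tracker$z_merge_nm,
                       sim$z_spacing_nm, sim$n_z)
  else detections
  tracks <- link_tracks(linked_input, cfg$tracker, dt_s = sim$dt_s)
  states <- classify_tracks(stack, tracks, cfg$classifier,
                            membrane_sampling = cfg$membrane_sampling)
  events <- extract_events(states, dt_s = sim$dt_s,
                           end_frame = sim$n_frames - 1L)
  summary <- tryCatch(summarize_times(events, cutoff_s = cfg$cutoff_s),
                      error = function(e) NULL)
  fit_one <- function(type) {
    dur <- events$duration_s[events$type == type]
    tryCatch(fit_exponential(dur, cfg$bin_width_s),
             error = function(e) NULL)
  }
  fit_des <- fit_one("desorption")
  fit_int <- fit_one("internalization")

  manifest <- list(
    mode = cfg$mode, seed = cfg$seed,
    n_frames = sim$n_frames, dt_s = sim$dt_s, pitch_nm = sim$pitch_nm,
    counts = list(episodes = nrow(log$episodes),
                  detections = nrow(detections),
                  track_points = nrow(tracks),
                  tracks = length(unique(tracks$track_id)),
                  classified_points = nrow(states),
                  events = nrow(events)),
    tau_desorption_s = if (!is.null(fit_des)) fit_des$tau_s else NA,
    tau_internalization_s = if (!is.null(fit_int)) fit_int$tau_s else NA,
    internalized_fraction = if (!is.null(summary))
      summary$internalized_fraction else NA)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    cfg_path <- file.path(out_dir, "config.json")
    jsonlite::write_json(list(mode = cfg$mode, seed = cfg$seed,
                              sim = unclass(sim),
                              tracker = unclass(cfg$tracker),
                              classifier = unclass(cfg$classifier),
                              bin_width_s = cfg$bin_width_s),
                         cfg_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    manifest$config_md5 <- unname(tools::md5sum(cfg_path))
    utils::write.csv(log$episodes, file.path(out_dir, "episodes_truth.csv"),
                     row.names = FALSE)
    utils::write.csv(detections, file.path(out_dir, "detections.csv"),
                     row.names = FALSE)
    utils::write.csv(tracks, file.path(out_dir, "tracks.csv"),
                     row.names = FALSE)
    utils::write.csv(states, file.path(out_dir, "states.csv"),
                     row.names = FALSE)
    utils::write.csv(events, file.path(out_dir, "events.csv"),
                     row.names = FALSE)
    fits <- list(desorption = fit_to_list(fit_des),
                 internalization = fit_to_list(fit_int))
    jsonlite::write_json(fits, file.path(out_dir, "fits.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    if (write_movie)
      write_fixture(stack, log, out_dir, overwrite = TRUE)
  }
  structure(list(log = log, stack = stack, detections = detections,
                 tracks = tracks, states = states, events = events,
                 summary = summary, fit_desorption = fit_des,
                 fit_internalization = fit_int, manifest = manifest),
            class = "pipeline_run")
}

fit_to_list <- function(fit) {
  if (is.null(fit)) return(NULL)
  fit[c("n_events", "n0", "tau_s", "se_tau_s", "bin_width_s", "tau_mle_s")]
}

#' @export
print.pipeline_run <- function(x, ...) {
  m <- x$manifest
  cat("<pipeline_run>", m$mode, "seed", m$seed, "\n")
  utils::str(m$counts, no.list = TRUE)
  if (is.finite(m$tau_desorption_s))
    cat(sprintf("  tau desorption: %.3g s\n", m$tau_desorption_s))
  if (is.finite(m$tau_internalization_s))
    cat(sprintf("  tau internalization: %.3g s\n", m$tau_internalization_s))
  invisible(x)
}
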