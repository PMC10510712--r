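#' Simulation configuration
#'
#' Assembles and validates the full parameter set of the synthetic
#' two-channel movie simulator. The three acquisition modes mirror the
#' imaging geometries of typical live-cell experiments on particle uptake:
#'
#' * `"confocal3d"` -- slow volumetric imaging: 3 z-planes spanning ~0.9 um,
#'   one stack every 15 s, 120 nm pixels, 40 time points.
#' * `"confocal2d"` -- fast single-plane imaging: one frame every 1.25 s,
#'   120 nm pixels, 80 frames.
#' * `"sted"` -- super-resolved single-plane imaging: 45 nm pixels,
#'   1.5 s frames, a narrow particle PSF.
#'
#' Membrane-residence kinetics are a competing-risks model: adsorption
#' episodes arrive as a Poisson process along the membrane with rate
#' `arrival_rate_per_um_s` (events per second per micrometre of membrane
#' contour); each episode dwells for an exponential time with total hazard
#' `k_off + k_int` and resolves to desorption with probability
#' `k_off / (k_off + k_int)`, otherwise to internalization. Internalized
#' particles are transported toward the cell interior at
#' `transport_speed_nm_s`, pausing in any given frame with probability
#' `pause_prob`, and may leave the cell again with hazard
#' `exit_hazard_per_s`. The slow modes default to minute-scale residence
#' (characteristic time ~15 s); the fast modes to seconds-scale residence
#' (characteristic time ~1.7 s), matching the time scales each acquisition
#' is able to resolve.
#'
#' @param mode acquisition preset, one of `"confocal2d"`, `"confocal3d"`,
#'   `"sted"`.
#' @param arena_um width and height of the field of view in micrometres.
#' @param cell_center_um cell centre (x, y) in micrometres; default arena
#'   centre.
#' @param cell_radii_um cell radii (x, y) in micrometres (equal = circle).
#' @param fourier_amp_um amplitude of a static low-order Fourier
#'   perturbation of the cell outline (0 = smooth ellipse).
#' @param fourier_mode angular order of the static perturbation.
#' @param drift_nm_per_frame amplitude of the slow sinusoidal membrane
#'   deformation, expressed as the largest radial displacement per frame.
#' @param drift_period_frames period of the membrane deformation.
#' @param arrival_rate_per_um_s adsorption arrival rate (events/s/um).
#' @param k_off desorption hazard (1/s).
#' @param k_int internalization hazard (1/s).
#' @param transport_speed_nm_s inward transport speed after entry (nm/s).
#' @param pause_prob per-frame probability that an internalized particle
#'   pauses instead of moving inward.
#' @param exit_hazard_per_s hazard (1/s) for an internalized particle to
#'   exit the cell again (it then disappears from the recording).
#' @param membrane_diffusion_um2_s lateral diffusion coefficient of
#'   adsorbed particles along the membrane (um^2/s).
#' @param free_diffusion_um2_s diffusion coefficient of particles in the
#'   medium after desorption (um^2/s); such particles leave the thin
#'   imaged volume almost immediately and are logged but not rendered.
#' @param dt_s frame interval in seconds.
#' @param n_frames number of time points.
#' @param n_z number of z-planes (1 or 3).
#' @param z_spacing_nm spacing between z-planes (nm).
#' @param pitch_nm pixel pitch (nm).
#' @param psf_sigma_membrane_nm,psf_sigma_particle_nm lateral PSF standard
#'   deviations per channel (nm).
#' @param psf_sigma_z_nm axial PSF standard deviation (nm); controls how a
#'   particle's intensity is shared between z-planes in 3D mode.
#' @param particle_photons expected photons collected from one particle per
#'   frame (in-focus).
#' @param membrane_peak_photons expected photon count at the crest of the
#'   membrane ridge.
#' @param photon_scale global multiplier on both photon budgets (0 turns
#'   the illumination off).
#' @param read_noise_sd standard deviation of additive Gaussian read noise
#'   (counts).
#' @param seed integer seed for the single RNG stream of the run.
#'
#' @return an object of class `simulation_config` (a validated named list).
#' @examples
#' cfg <- simulation_config(mode = "confocal2d", n_frames = 10, seed = 1)
#' cfg$dt_s
#' @export
simulation_config <- function(mode = c("confocal2d", "confocal3d", "sted"),
                              arena_um = c(24, 24),
                              cell_center_um = arena_um / 2,
                              cell_radii_um = c(8, 8),
                              fourier_amp_um = 0,
                              fourier_mode = 3,
                              drift_nm_per_frame = 10,
                              drift_period_frames = 60,
                              arrival_rate_per_um_s = NULL,
                              k_off = NULL,
                              k_int = NULL,
                              transport_speed_nm_s = 200,
                              pause_prob = 0.2,
                              exit_hazard_per_s = 0.002,
                              membrane_diffusion_um2_s = 0.005,
                              free_diffusion_um2_s = 2,
                              dt_s = NULL,
                              n_frames = NULL,
                              n_z = NULL,
                              z_spacing_nm = 450,
                              pitch_nm = NULL,
                              psf_sigma_membrane_nm = NULL,
                              psf_sigma_particle_nm = NULL,
                              psf_sigma_z_nm = 350,
                              particle_photons = 5000,
                              membrane_peak_photons = 300,
                              photon_scale = 1,
                              read_noise_sd = 3,
                              seed = 1L) {
  mode <- match.arg(mode)
  defaults <- switch(mode,
    confocal3d = list(dt_s = 15, n_frames = 40, n_z = 3, pitch_nm = 120,
                      psf_m = 160, psf_p = 130,
                      k_off = 0.055, k_int = 0.008, rate = 0.004),
    confocal2d = list(dt_s = 1.25, n_frames = 80, n_z = 1, pitch_nm = 120,
                      psf_m = 160, psf_p = 130,
                      k_off = 0.5, k_int = 0.1, rate = 0.03),
    sted = list(dt_s = 1.5, n_frames = 80, n_z = 1, pitch_nm = 45,
                psf_m = 60, psf_p = 30,
                k_off = 0.5, k_int = 0.1, rate = 0.03))
  cfg <- list(
    mode = mode,
    arena_um = as.numeric(arena_um),
    cell_center_um = as.numeric(cell_center_um),
    cell_radii_um = as.numeric(cell_radii_um),
    fourier_amp_um = fourier_amp_um,
    fourier_mode = as.integer(fourier_mode),
    drift_nm_per_frame = drift_nm_per_frame,
    drift_period_frames = drift_period_frames,
    arrival_rate_per_um_s = arrival_rate_per_um_s %||% defaults$rate,
    k_off = k_off %||% defaults$k_off,
    k_int = k_int %||% defaults$k_int,
    transport_speed_nm_s = transport_speed_nm_s,
    pause_prob = pause_prob,
    exit_hazard_per_s = exit_hazard_per_s,
    membrane_diffusion_um2_s = membrane_diffusion_um2_s,
    free_diffusion_um2_s = free_diffusion_um2_s,
    dt_s = dt_s %||% defaults$dt_s,
    n_frames = as.integer(n_frames %||% defaults$n_frames),
    n_z = as.integer(n_z %||% defaults$n_z),
    z_spacing_nm = z_spacing_nm,
    pitch_nm = pitch_nm %||% defaults$pitch_nm,
    psf_sigma_membrane_nm = psf_sigma_membrane_nm %||% defaults$psf_m,
    psf_sigma_particle_nm = psf_sigma_particle_nm %||% defaults$psf_p,
    psf_sigma_z_nm = psf_sigma_z_nm,
    particle_photons = particle_photons,
    membrane_peak_photons = membrane_peak_photons,
    photon_scale = photon_scale,
    read_noise_sd = read_noise_sd,
    seed = as.integer(seed))
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_simulation_config <- function(cfg) {
  for (nm in c("arrival_rate_per_um_s", "k_off", "k_int", "exit_hazard_per_s",
               "transport_speed_nm_s", "membrane_diffusion_um2_s", "free_diffusion_um2_s",
               "particle_photons", "membrane_peak_photons", "photon_scale",
               "read_noise_sd", "drift_nm_per_frame"))
    check_number(cfg[[nm]], nm, min = 0)
  check_number(cfg$dt_s, "dt_s", min = 0, strict = TRUE)
  check_number(cfg$pitch_nm, "pitch_nm", min = 0, strict = TRUE)
  check_number(cfg$z_spacing_nm, "z_spacing_nm", min = 0, strict = TRUE)
  if (cfg$n_frames < 1L) stop_config("n_frames must be >= 1")
  if (!cfg$n_z %in% c(1L, 3L)) stop_config("n_z must be 1 or 3")
  if (cfg$pause_prob < 0 || cfg$pause_prob > 1)
    stop_config("pause_prob must be in [0, 1]")
  if (length(cfg$arena_um) != 2L || any(cfg$arena_um <= 0))
    stop_config("arena_um must be two positive lengths")
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>", x$mode, "\n",
      sprintf(" %d frames x %.3g s, %d z-plane(s), %g nm pixels\n",
              x$n_frames, x$dt_s, x$n_z, x$pitch_nm),
      sprintf(" kinetics: k_off=%g/s k_int=%g/s arrivals=%g /um/s\n",
              x$k_off, x$k_int, x$arrival_rate_per_um_s),
      sprintf(" seed: %d\n", x$seed))
  invisible(x)
}

#' Trajectory-linking configuration
#'
#' The maximum linking distance defaults to twice the estimated object
#' size used in practice for 40, 100 and 200 nm particles: 0.8, 1.4 and
#' 2.4 um respectively. Gap closing is never permitted: a track that
#' fails to find a match terminates and is never resumed.
#'
#' @param particle_size_nm nominal particle diameter (40, 100 or 200);
#'   used only to pick the default linking distance.
#' @param max_link_nm maximum frame-to-frame linking distance in nm;
#'   overrides the size-based default.
#' @param z_merge_nm lateral distance below which detections in adjacent
#'   z-planes of the same time point are treated as one object
#'   (default half the linking distance).
#' @return an object of class `tracker_config`.
#' @examples
#' tracker_config(100)$max_link_nm  # 1400
#' @export
tracker_config <- function(particle_size_nm = 100, max_link_nm = NULL,
                           z_merge_nm = NULL) {
  default_cap <- c(`40` = 800, `100` = 1400, `200` = 2400)
  if (is.null(max_link_nm)) {
    key <- as.character(particle_size_nm)
    if (!key %in% names(default_cap))
      stop_config("no default linking distance for particle size ",
                  particle_size_nm, " nm; give max_link_nm explicitly")
    max_link_nm <- unname(default_cap[key])
  }
  check_number(max_link_nm, "max_link_nm", min = 0, strict = TRUE)
  structure(list(particle_size_nm = particle_size_nm,
                 max_link_nm = max_link_nm,
                 z_merge_nm = z_merge_nm %||% (max_link_nm / 2),
                 gap_closing = FALSE,
                 policy = "optimal_assignment"),
            class = "tracker_config")
}

#' State-classification configuration
#'
#' A particle is called internalized when its intensity peak lies at least
#' `threshold_nm` past the membrane peak toward the cell interior
#' (2 pixels: 240 nm at 120 nm confocal pitch, 90 nm at 45 nm STED pitch),
#' adsorbed when the two peaks coincide within `adsorption_window_nm`
#' (default one pixel), and free when it lies outside the membrane by more
#' than the window. Separations between the window and the threshold are
#' conservatively kept as adsorbed, so that a particle still sitting in a
#' membrane invagination that has not yet pinched off is not counted as
#' internalized.
#'
#' @param pitch_nm pixel pitch in nm.
#' @param k_pixels number of pixels defining the internalization
#'   threshold (default 2).
#' @param adsorption_window_nm half-width (nm) of the peak-coincidence
#'   window; default one pixel pitch.
#' @return an object of class `classifier_config`.
#' @examples
#' classifier_config(120)$threshold_nm  # 240
#' @export
classifier_config <- function(pitch_nm = 120, k_pixels = 2,
                              adsorption_window_nm = pitch_nm) {
  threshold <- compute_separation_threshold(pitch_nm, k_pixels)
  check_number(adsorption_window_nm, "adsorption_window_nm",
               min = 0, strict = TRUE)
  if (threshold <= adsorption_window_nm)
    stop_config("internalization threshold (", threshold,
                " nm) must exceed the adsorption window (",
                adsorption_window_nm, " nm)")
  structure(list(pitch_nm = pitch_nm, k_pixels = k_pixels,
                 threshold_nm = threshold,
                 adsorption_window_nm = adsorption_window_nm),
            class = "classifier_config")
}
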