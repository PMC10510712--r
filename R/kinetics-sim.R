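## Cell geometry -------------------------------------------------------------

## Radial perturbation (nm) of the cell outline at angles theta (radians)
## and frame index t (0-based). The slow deformation is sinusoidal in time;
## its amplitude is chosen so that the largest radial displacement between
## consecutive frames equals drift_nm_per_frame.
contour_radial_offset_nm <- function(cfg, theta, frame) {
  static <- cfg$fourier_amp_um * 1000 * cos(cfg$fourier_mode * theta)
  if (cfg$drift_nm_per_frame <= 0) return(static)
  omega <- 2 * pi / cfg$drift_period_frames
  amp <- cfg$drift_nm_per_frame / (2 * sin(omega / 2))
  static + amp * sin(cfg$fourier_mode * theta + omega * frame)
}

#' Cell contour points of a simulation at a given frame
#'
#' Returns positions (nm) on the closed cell outline at parameter angles
#' `theta`, together with outward unit normals, for the (slowly deforming)
#' cell shape of a simulation configuration.
#'
#' @param cfg a [simulation_config()].
#' @param theta angles in radians.
#' @param frame 0-based frame index (the outline deforms slowly in time).
#' @return data.frame with columns `theta`, `x_nm`, `y_nm`, `nx`, `ny`.
#' @export
cell_contour <- function(cfg, theta, frame = 0) {
  cx <- cfg$cell_center_um[1] * 1000
  cy <- cfg$cell_center_um[2] * 1000
  rx <- cfg$cell_radii_um[1] * 1000
  ry <- cfg$cell_radii_um[2] * 1000
  dr <- contour_radial_offset_nm(cfg, theta, frame)
  x <- cx + (rx + dr) * cos(theta)
  y <- cy + (ry + dr) * sin(theta)
  ## numerical tangent -> outward normal
  eps <- 1e-4
  dr2 <- contour_radial_offset_nm(cfg, theta + eps, frame)
  x2 <- cx + (rx + dr2) * cos(theta + eps)
  y2 <- cy + (ry + dr2) * sin(theta + eps)
  tx <- x2 - x; ty <- y2 - y
  len <- sqrt(tx^2 + ty^2)
  nx <- ty / len; ny <- -tx / len
  ## orient away from the centre
  flip <- (nx * (x - cx) + ny * (y - cy)) < 0
  nx[flip] <- -nx[flip]; ny[flip] <- -ny[flip]
  data.frame(theta = theta, x_nm = x, y_nm = y, nx = nx, ny = ny)
}

## approximate membrane perimeter (um) at frame 0
contour_perimeter_um <- function(cfg, n = 2048) {
  th <- seq(0, 2 * pi, length.out = n + 1)
  p <- cell_contour(cfg, th, 0)
  sum(sqrt(diff(p$x_nm)^2 + diff(p$y_nm)^2)) / 1000
}

## z coordinates (nm) of the imaged planes, centred on 0
plane_z_nm <- function(cfg) (seq_len(cfg$n_z) - (cfg$n_z + 1) / 2) * cfg$z_spacing_nm

## Kinetics ------------------------------------------------------------------

#' Simulate membrane-residence kinetics with known ground truth
#'
#' Draws adsorption episodes as a Poisson process along the cell membrane
#' and resolves each one by competing exponential risks: the dwell time is
#' exponential with total hazard `k_off + k_int`, and the episode ends in
#' desorption with probability `k_off / (k_off + k_int)`, otherwise in
#' internalization. Episodes still ongoing at the final frame are marked
#' censored. Internalized particles are transported toward the cell
#' interior (with pauses) and may exit again; desorbed particles diffuse
#' in the medium. The continuous-time history is sampled at the frame
#' times of the configured acquisition.
#'
#' @param cfg a [simulation_config()].
#' @return an object of class `ground_truth_log`: a list with
#'   \describe{
#'     \item{episodes}{one row per adsorption episode: `particle_id`,
#'       `theta`, `t_adsorb_s`, `dwell_s` (continuous), `outcome`
#'       (`"desorb"`, `"internalize"` or `"censored"`), `first_frame`,
#'       `last_frame` (first/last frame sampled in the adsorbed state; NA
#'       if the episode falls entirely between frames), `observable`.}
#'     \item{frames}{per particle and frame: `particle_id`, `frame`,
#'       `t_s`, `x_nm`, `y_nm`, `z_nm`, `state` in
#'       free/adsorbed/internalized/exited.}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' log <- simulate_kinetics(simulation_config(n_frames = 20, seed = 2))
#' table(log$episodes$outcome)
#' @export
simulate_kinetics <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  validate_simulation_config(cfg)
  set.seed(cfg$seed)

  dt <- cfg$dt_s
  n_frames <- cfg$n_frames
  t_last <- (n_frames - 1) * dt
  t_total <- n_frames * dt
  hazard <- cfg$k_off + cfg$k_int

  perim <- contour_perimeter_um(cfg)
  ## arrivals as sequential Poisson-process increments, and all episode-level
  ## marks drawn before any frame-level randomness: extending n_frames at the
  ## same seed extends the episode list instead of reshuffling it
  rate_tot <- cfg$arrival_rate_per_um_s * perim
  zs <- plane_z_nm(cfg)
  z_half <- max(abs(zs)) + cfg$z_spacing_nm / 4
  arr <- numeric(0)
  marks <- list()
  if (rate_tot > 0) {
    t_acc <- 0
    repeat {
      t_acc <- t_acc + stats::rexp(1, rate_tot)
      if (t_acc > t_total) break
      arr <- c(arr, t_acc)
      marks[[length(arr)]] <- list(
        theta = stats::runif(1, 0, 2 * pi),
        dwell = if (hazard > 0) stats::rexp(1, hazard) else Inf,
        internalize = hazard > 0 && stats::runif(1) < cfg$k_int / hazard,
        z0 = if (cfg$n_z > 1) stats::runif(1, -z_half, z_half) else 0)
    }
  }
  n_arr <- length(arr)

  episodes <- vector("list", n_arr)
  frames <- vector("list", n_arr)
  if (n_arr > 0) for (i in seq_len(n_arr)) {
    t_a <- arr[i]
    theta <- marks[[i]]$theta
    dwell <- marks[[i]]$dwell
    internalize <- marks[[i]]$internalize
    t_end <- t_a + dwell
    z0 <- marks[[i]]$z0

    ads_f <- which((0:(n_frames - 1)) * dt >= t_a &
                   (0:(n_frames - 1)) * dt < t_end) - 1L
    observable <- length(ads_f) > 0
    censored <- t_end > t_last
    outcome <- if (censored) "censored" else if (internalize) "internalize" else "desorb"
    episodes[[i]] <- data.frame(
      particle_id = i, theta = theta, t_adsorb_s = t_a, dwell_s = dwell,
      t_end_s = t_end, outcome = outcome,
      first_frame = if (observable) ads_f[1] else NA_integer_,
      last_frame = if (observable) ads_f[length(ads_f)] else NA_integer_,
      observable = observable)
    if (!observable) next

    ## adsorbed positions: the anchor angle diffuses along the membrane
    n_ads <- length(ads_f)
    r_local <- mean(cfg$cell_radii_um) * 1000
    step_sd <- sqrt(2 * cfg$membrane_diffusion_um2_s * dt) * 1000
    theta_t <- theta + cumsum(c(0, stats::rnorm(n_ads - 1, 0, step_sd / r_local)))
    px <- numeric(n_ads); py <- numeric(n_ads)
    for (k in seq_len(n_ads)) {
      p <- cell_contour(cfg, theta_t[k], ads_f[k])
      px[k] <- p$x_nm; py[k] <- p$y_nm
    }
    rec <- data.frame(particle_id = i, frame = ads_f, t_s = ads_f * dt,
                      x_nm = px, y_nm = py, z_nm = z0, state = "adsorbed")

    post_f <- if (ads_f[length(ads_f)] + 1L <= n_frames - 1L)
      (ads_f[length(ads_f)] + 1L):(n_frames - 1L) else integer(0)
    if (!censored && length(post_f)) {
      if (internalize) {
        ## inward transport from the (moving) anchor point, with pauses,
        ## until exit or the end of the movie
        t_exit <- t_end + if (cfg$exit_hazard_per_s > 0)
          stats::rexp(1, cfg$exit_hazard_per_s) else Inf
        th_end <- theta_t[n_ads]
        depth <- 0
        max_depth <- 0.8 * min(cfg$cell_radii_um) * 1000
        drec <- vector("list", length(post_f))
        for (j in seq_along(post_f)) {
          f <- post_f[j]
          t_f <- f * dt
          if (t_f >= t_exit) {
            drec[[j]] <- data.frame(particle_id = i, frame = f, t_s = t_f,
                                    x_nm = NA_real_, y_nm = NA_real_,
                                    z_nm = z0, state = "exited")
            next
          }
          moved <- if (stats::runif(1) < cfg$pause_prob) 0 else dt
          depth <- min(depth + cfg$transport_speed_nm_s *
                         (if (j == 1) t_f - t_end else moved), max_depth)
          p <- cell_contour(cfg, th_end, f)
          drec[[j]] <- data.frame(particle_id = i, frame = f, t_s = t_f,
                                  x_nm = p$x_nm - depth * p$nx,
                                  y_nm = p$y_nm - depth * p$ny,
                                  z_nm = z0, state = "internalized")
        }
        rec <- rbind(rec, do.call(rbind, drec))
      } else {
        ## free diffusion in the medium after desorption
        n_post <- length(post_f)
        sd_nm <- sqrt(2 * cfg$free_diffusion_um2_s * dt) * 1000
        x0 <- px[n_ads]; y0 <- py[n_ads]
        fx <- x0 + cumsum(stats::rnorm(n_post, 0, sd_nm))
        fy <- y0 + cumsum(stats::rnorm(n_post, 0, sd_nm))
        rec <- rbind(rec, data.frame(particle_id = i, frame = post_f,
                                     t_s = post_f * dt, x_nm = fx, y_nm = fy,
                                     z_nm = z0, state = "free"))
      }
    }
    frames[[i]] <- rec
  }

  episodes <- if (n_arr > 0) do.call(rbind, episodes) else
    data.frame(particle_id = integer(0), theta = numeric(0),
               t_adsorb_s = numeric(0), dwell_s = numeric(0),
               t_end_s = numeric(0), outcome = character(0),
               first_frame = integer(0), last_frame = integer(0),
               observable = logical(0))
  frames <- do.call(rbind, frames[!vapply(frames, is.null, logical(1))])
  if (is.null(frames))
    frames <- data.frame(particle_id = integer(0), frame = integer(0),
                         t_s = numeric(0), x_nm = numeric(0), y_nm = numeric(0),
                         z_nm = numeric(0), state = character(0))
  rownames(episodes) <- rownames(frames) <- NULL
  structure(list(episodes = episodes, frames = frames, config = cfg),
            class = "ground_truth_log")
}

#' @export
print.ground_truth_log <- function(x, ...) {
  cat("<ground_truth_log>", nrow(x$episodes), "episodes,",
      nrow(x$frames), "particle-frames\n")
  if (nrow(x$episodes)) print(table(outcome = x$episodes$outcome))
  invisible(x)
}

## Hand-built scenes ---------------------------------------------------------

#' Ground-truth log for particles held at fixed depths
#'
#' Builds a deterministic log in which each particle sits motionless for
#' the whole movie at a stated depth relative to the membrane (0 = on the
#' membrane crest, positive = into the cell, negative = outside). Useful
#' for classifier calibration: the true separation of every particle is
#' known exactly. Membrane drift is disabled for these scenes.
#'
#' @param cfg a [simulation_config()].
#' @param depth_nm numeric vector of signed depths.
#' @param theta anchor angles (recycled against `depth_nm`).
#' @return a `ground_truth_log`; the nominal per-frame state follows the
#'   operational definitions: `"internalized"` from two pixels into the
#'   cell, `"free"` beyond one pixel outside the membrane, `"adsorbed"`
#'   in between. All particles are rendered (they sit in the imaged
#'   slab).
#' @export
static_depth_log <- function(cfg, depth_nm, theta = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  n <- length(depth_nm)
  if (is.null(theta)) theta <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  theta <- rep_len(theta, n)
  cfg$drift_nm_per_frame <- 0
  ## nominal states follow the operational definitions: internalized only
  ## from two pixels into the cell, free beyond one pixel outside
  state <- ifelse(depth_nm >= 2 * cfg$pitch_nm, "internalized",
                  ifelse(depth_nm < -cfg$pitch_nm, "free", "adsorbed"))
  empty_frames <- data.frame(particle_id = integer(0), frame = integer(0),
                             t_s = numeric(0), x_nm = numeric(0),
                             y_nm = numeric(0), z_nm = numeric(0),
                             state = character(0))
  frames <- if (n == 0) empty_frames else
    do.call(rbind, lapply(seq_len(n), function(i) {
    p <- cell_contour(cfg, theta[i], 0)
    data.frame(particle_id = i, frame = 0:(cfg$n_frames - 1),
               t_s = (0:(cfg$n_frames - 1)) * cfg$dt_s,
               x_nm = p$x_nm - depth_nm[i] * p$nx,
               y_nm = p$y_nm - depth_nm[i] * p$ny,
               z_nm = 0, state = state[i])
  }))
  episodes <- data.frame(particle_id = seq_len(n), theta = theta,
                         t_adsorb_s = rep(0, n), dwell_s = rep(Inf, n),
                         t_end_s = rep(Inf, n),
                         outcome = rep("censored", n),
                         first_frame = rep(0L, n),
                         last_frame = rep(cfg$n_frames - 1L, n),
                         observable = rep(TRUE, n))
  structure(list(episodes = episodes, frames = frames, config = cfg,
                 depth_nm = depth_nm,
                 ## membrane-proximal particles are in the imaged slab even
                 ## when just outside the cell, so render them regardless
                 render_states = c("free", "adsorbed", "internalized")),
            class = "ground_truth_log")
}

#' Synthetic tracks of particles immobilized on glass
#'
#' Emulates the standard localization-precision control: stationary
#' particles adsorbed on a coverslip, relocalized every frame with
#' isotropic Gaussian error. Returns ready-made tracks, bypassing
#' rendering, so the per-axis error is known exactly.
#'
#' @param n_tracks number of particles.
#' @param n_frames frames per track.
#' @param sigma_nm per-axis localization error (nm).
#' @param spacing_nm grid spacing between particles.
#' @param seed RNG seed.
#' @return data.frame with `track_id`, `frame`, `x_nm`, `y_nm` as produced
#'   by [link_tracks()].
#' @examples
#' tr <- simulate_glass_tracks(5, 10, sigma_nm = 10, seed = 1)
#' estimate_localization_precision(tr)
#' @export
simulate_glass_tracks <- function(n_tracks, n_frames, sigma_nm,
                                  spacing_nm = 5000, seed = 1L) {
  check_number(sigma_nm, "sigma_nm", min = 0)
  set.seed(seed)
  side <- ceiling(sqrt(n_tracks))
  out <- lapply(seq_len(n_tracks), function(i) {
    x0 <- ((i - 1) %% side) * spacing_nm
    y0 <- ((i - 1) %/% side) * spacing_nm
    data.frame(track_id = i, frame = 0:(n_frames - 1),
               x_nm = x0 + stats::rnorm(n_frames, 0, sigma_nm),
               y_nm = y0 + stats::rnorm(n_frames, 0, sigma_nm))
  })
  do.call(rbind, out)
}
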