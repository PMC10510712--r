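#' Two-channel movie container
#'
#' Thin container around a `(T, Z, C, Y, X)` intensity array with the
#' physical metadata needed to interpret it.
#'
#' @param data numeric array with dimensions time, z-plane, channel, rows,
#'   columns; channel 1 is the membrane stain, channel 2 the particles.
#' @param pitch_nm pixel pitch (nm).
#' @param z_spacing_nm z-plane spacing (nm).
#' @param dt_s frame interval (s).
#' @return an object of class `movie_stack`.
#' @export
movie_stack <- function(data, pitch_nm, z_spacing_nm, dt_s) {
  if (length(dim(data)) != 5L) stop_config("data must be a 5-d (T,Z,C,Y,X) array")
  if (any(!is.finite(data)) || any(data < 0))
    stop_config("intensities must be finite and non-negative")
  check_number(pitch_nm, "pitch_nm", min = 0, strict = TRUE)
  check_number(dt_s, "dt_s", min = 0, strict = TRUE)
  structure(list(data = data, pitch_nm = pitch_nm,
                 z_spacing_nm = z_spacing_nm, dt_s = dt_s,
                 channels = c(membrane = 1L, particle = 2L)),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<movie_stack> %d frames, %d z, %d channels, %dx%d px @ %g nm, dt %g s\n",
              d[1], d[2], d[3], d[4], d[5], x$pitch_nm, x$dt_s))
  invisible(x)
}

## one (Y, X) frame as a plain matrix
frame_image <- function(stack, frame, channel = c("membrane", "particle"), z = 1L) {
  channel <- match.arg(channel)
  stack$data[frame + 1L, z, stack$channels[[channel]], , ]
}

## accumulate unit-mass points into an image by bilinear splatting
splat_points <- function(nr, nc, x_px, y_px, w) {
  keep <- x_px > -1 & x_px < nc & y_px > -1 & y_px < nr
  x_px <- x_px[keep]; y_px <- y_px[keep]; w <- w[keep]
  img <- matrix(0, nr, nc)
  if (!length(x_px)) return(img)
  x0 <- floor(x_px); y0 <- floor(y_px)
  fx <- x_px - x0; fy <- y_px - y0
  add <- function(xx, yy, ww) {
    ok <- xx >= 0 & xx <= nc - 1 & yy >= 0 & yy <= nr - 1 & ww > 0
    if (!any(ok)) return()
    idx <- xx[ok] * nr + yy[ok] + 1
    s <- rowsum(ww[ok], idx)
    img[as.numeric(rownames(s))] <<- img[as.numeric(rownames(s))] + s[, 1]
  }
  add(x0, y0, w * (1 - fx) * (1 - fy))
  add(x0 + 1, y0, w * fx * (1 - fy))
  add(x0, y0 + 1, w * (1 - fx) * fy)
  add(x0 + 1, y0 + 1, w * fx * fy)
  img
}

## pixel-integrated isotropic Gaussian spot added in place
add_spot <- function(img, x_px, y_px, sigma_px, photons) {
  nr <- nrow(img); nc <- ncol(img)
  hw <- ceiling(5 * sigma_px)
  cx <- round(x_px); cy <- round(y_px)
  cols <- max(0, cx - hw):min(nc - 1, cx + hw)
  rows <- max(0, cy - hw):min(nr - 1, cy + hw)
  if (!length(cols) || !length(rows)) return(img)
  px_x <- stats::pnorm((cols + 0.5 - x_px) / sigma_px) -
    stats::pnorm((cols - 0.5 - x_px) / sigma_px)
  px_y <- stats::pnorm((rows + 0.5 - y_px) / sigma_px) -
    stats::pnorm((rows - 0.5 - y_px) / sigma_px)
  img[rows + 1, cols + 1] <- img[rows + 1, cols + 1] + photons * outer(px_y, px_x)
  img
}

#' Render a ground-truth log into a two-channel movie
#'
#' The membrane channel draws the cell outline as a ridge with a Gaussian
#' cross-section (the diffraction-limited image of a thin membrane); the
#' particle channel draws every membrane-bound or internalized particle as
#' a pixel-integrated Gaussian spot. Desorbed (free) particles diffuse out
#' of the thin imaged volume within a fraction of a frame and are
#' therefore not rendered. With `noise = TRUE`, Poisson photon noise and
#' additive Gaussian read noise are applied and the result is digitized to
#' integer counts (clipped to the 16-bit camera range), emulating a photon
#' counting acquisition.
#'
#' @param log a `ground_truth_log` from [simulate_kinetics()] or
#'   [static_depth_log()].
#' @param cfg the [simulation_config()] used to generate the log.
#' @param noise apply Poisson + Gaussian noise and digitize (default TRUE).
#' @return a [movie_stack()].
#' @export
render_movie <- function(log, cfg = log$config, noise = TRUE) {
  stopifnot(inherits(log, "ground_truth_log"), inherits(cfg, "simulation_config"))
  if (cfg$pitch_nm > 4 * cfg$psf_sigma_particle_nm)
    warning("pixel pitch exceeds 4x the particle PSF sigma: spots are undersampled")
  pitch <- cfg$pitch_nm
  nc <- round(cfg$arena_um[1] * 1000 / pitch)
  nr <- round(cfg$arena_um[2] * 1000 / pitch)
  n_t <- cfg$n_frames; n_z <- cfg$n_z
  sig_m <- cfg$psf_sigma_membrane_nm / pitch
  sig_p <- cfg$psf_sigma_particle_nm / pitch
  zs <- plane_z_nm(cfg)
  amp_m <- cfg$membrane_peak_photons * cfg$photon_scale
  amp_p <- cfg$particle_photons * cfg$photon_scale

  if (noise) set.seed(cfg$seed + 1L)  # noise stream, distinct from kinetics
  arr <- array(0, dim = c(n_t, n_z, 2L, nr, nc))
  perim_px <- contour_perimeter_um(cfg) * 1000 / pitch
  n_samp <- max(64L, ceiling(perim_px * 4))
  th <- seq(0, 2 * pi, length.out = n_samp + 1)[-1]
  render_states <- log$render_states %||% c("adsorbed", "internalized")
  vis <- log$frames[log$frames$state %in% render_states, , drop = FALSE]

  for (t in seq_len(n_t) - 1L) {
    mem <- matrix(0, nr, nc)
    if (amp_m > 0) {
      p <- cell_contour(cfg, th, t)
      acc <- splat_points(nr, nc, p$x_nm / pitch, p$y_nm / pitch,
                          rep(perim_px / n_samp, n_samp))
      acc <- EBImage::gblur(acc, sigma = sig_m, radius = 2 * ceiling(3 * sig_m) + 1)
      mem <- pmax(amp_m * sqrt(2 * pi) * sig_m * acc, 0)  # FFT blur can ring slightly negative
    }
    pf <- vis[vis$frame == t, , drop = FALSE]
    for (z in seq_len(n_z)) {
      par_img <- matrix(0, nr, nc)
      if (amp_p > 0 && nrow(pf)) for (k in seq_len(nrow(pf))) {
        zfac <- if (n_z > 1)
          exp(-(zs[z] - pf$z_nm[k])^2 / (2 * cfg$psf_sigma_z_nm^2)) else 1
        par_img <- add_spot(par_img, pf$x_nm[k] / pitch, pf$y_nm[k] / pitch,
                            sig_p, amp_p * zfac)
      }
      if (noise) {
        mem_z <- digitize_frame(mem, cfg$read_noise_sd)
        par_z <- digitize_frame(par_img, cfg$read_noise_sd)
      } else {
        mem_z <- mem; par_z <- par_img
      }
      arr[t + 1L, z, 1L, , ] <- mem_z
      arr[t + 1L, z, 2L, , ] <- par_z
    }
  }
  movie_stack(arr, pitch_nm = pitch, z_spacing_nm = cfg$z_spacing_nm,
              dt_s = cfg$dt_s)
}

## Poisson shot noise + Gaussian read noise, digitized to 16-bit counts
digitize_frame <- function(img, read_sd) {
  v <- stats::rpois(length(img), pmax(img, 0))
  if (read_sd > 0) v <- v + stats::rnorm(length(img), 0, read_sd)
  matrix(pmin(65535, pmax(0, round(v))), nrow(img), ncol(img))
}
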