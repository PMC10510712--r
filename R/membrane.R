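#' Internalization separation threshold
#'
#' A particle is only called internalized when its intensity peak is
#' displaced from the membrane peak toward the cell interior by at least
#' `k_pixels` pixels: 2 pixels is 240 nm at the 120 nm confocal pitch and
#' 90 nm at the 45 nm STED pitch. Because each peak may sit anywhere
#' within its pixel, the guaranteed physical separation is about
#' 1.5 pixels (180 nm at confocal pitch).
#'
#' @param pixel_pitch_nm pixel pitch (nm).
#' @param k_pixels threshold in pixels.
#' @return the threshold in nm.
#' @examples
#' compute_separation_threshold(120, 2)   # 240
#' compute_separation_threshold(45, 2)    # 90
#' compute_separation_threshold(120, 1.5) # 180
#' @export
compute_separation_threshold <- function(pixel_pitch_nm, k_pixels = 2) {
  check_number(pixel_pitch_nm, "pixel_pitch_nm", min = 0, strict = TRUE)
  check_number(k_pixels, "k_pixels", min = 0, strict = TRUE)
  pixel_pitch_nm * k_pixels
}

## smooth + Otsu binarization of a membrane image
binarize_membrane <- function(image, smooth_sigma_px = 2) {
  sm <- EBImage::gblur(image, sigma = smooth_sigma_px,
                       radius = 2 * ceiling(3 * smooth_sigma_px) + 1)
  mx <- max(sm)
  if (mx <= 0) return(matrix(FALSE, nrow(image), ncol(image)))
  thr <- EBImage::otsu(EBImage::Image(sm / mx))
  matrix(sm / mx > thr, nrow(image), ncol(image))
}

#' Extract the outer cell membrane contour from a membrane-stain frame
#'
#' The frame is smoothed and thresholded (Otsu); the largest connected
#' component is taken as the cell, its filled footprint as the cell
#' interior, and its boundary -- refined to the crest of the membrane
#' ridge with subpixel precision -- as the membrane contour. Each contour
#' point carries an outward unit normal and a "well defined" flag that is
#' set where the local ridge intensity exceeds the image background by a
#' configurable multiple of the background noise; downstream profile
#' analysis uses only well-defined points.
#'
#' @param membrane_image numeric matrix (membrane channel of one frame).
#' @param pitch_nm pixel pitch (nm).
#' @param smooth_sigma_px Gaussian smoothing before thresholding.
#' @param min_area_px minimum component area to accept as a cell.
#' @param contrast_mult ridge contrast required, in units of background
#'   noise (robust SD), for a point to count as well defined.
#' @return an object of class `membrane_contour`: list with `points`
#'   (data.frame `x_nm`, `y_nm`, `nx`, `ny`, `well_defined`), `interior`
#'   (logical matrix), and `pitch_nm`.
#' @export
extract_membrane_contour <- function(membrane_image, pitch_nm,
                                     smooth_sigma_px = 2,
                                     min_area_px = 200,
                                     contrast_mult = 5) {
  if (!is.matrix(membrane_image)) stop_config("membrane_image must be a matrix")
  check_number(pitch_nm, "pitch_nm", min = 0, strict = TRUE)
  nr <- nrow(membrane_image); nc <- ncol(membrane_image)
  sm <- EBImage::gblur(membrane_image, sigma = smooth_sigma_px,
                       radius = 2 * ceiling(3 * smooth_sigma_px) + 1)
  bin <- binarize_membrane(membrane_image, smooth_sigma_px)
  lab <- EBImage::bwlabel(EBImage::Image(bin * 1))
  sizes <- tabulate(as.integer(lab))
  if (!length(sizes) || max(sizes) < min_area_px)
    stop(structure(class = c("nanodwell_no_cell", "error", "condition"),
                   list(message = "no cell found in membrane channel",
                        call = sys.call())))
  comp <- matrix(as.integer(lab) == which.max(sizes), nr, nc)
  interior <- matrix(as.logical(EBImage::fillHull(EBImage::Image(comp * 1)) > 0),
                     nr, nc)
  oc <- EBImage::ocontour(EBImage::Image(interior * 1))[[1]]
  ## ocontour returns 0-based (dim1, dim2) = (row, col) indices
  ry <- oc[, 1]; cx <- oc[, 2]
  n <- length(ry)
  if (n < 8L)
    stop(structure(class = c("nanodwell_no_cell", "error", "condition"),
                   list(message = "cell boundary too short", call = sys.call())))
  ## circular smoothing of the polyline before tangent estimation
  win <- min(7L, n - (1 - n %% 2))
  csmooth <- function(v) {
    k <- rep(1 / win, win)
    stats::filter(c(v[(n - win):n], v, v[1:win]), k)[(win + 2):(win + 1 + n)]
  }
  sy <- csmooth(ry); sx <- csmooth(cx)
  ## tangents by central differences over +-2 points (circular)
  sh <- function(v, k) v[((seq_len(n) - 1 + k) %% n) + 1]
  tx <- sh(sx, 2) - sh(sx, -2)
  ty <- sh(sy, 2) - sh(sy, -2)
  len <- sqrt(tx^2 + ty^2); len[len == 0] <- 1
  nx <- ty / len; ny <- -tx / len
  ## orient outward: the point 2 px along the normal must leave the interior
  probe_r <- pmin(pmax(round(sy + 2 * ny), 0), nr - 1)
  probe_c <- pmin(pmax(round(sx + 2 * nx), 0), nc - 1)
  inside <- interior[cbind(probe_r + 1, probe_c + 1)]
  nx[inside] <- -nx[inside]; ny[inside] <- -ny[inside]
  ## refine each point to the crest of the smoothed ridge along its normal
  off <- seq(-4, 4, by = 0.25)
  crest_s <- numeric(n); crest_val <- numeric(n)
  for (i in seq_len(n)) {
    vals <- bilinear_sample(sm, sx[i] + off * nx[i], sy[i] + off * ny[i])
    vals[is.na(vals)] <- -Inf
    k <- which.max(vals)
    crest_val[i] <- vals[k]
    crest_s[i] <- off[1] + (refine_peak(vals, k) - 1) * 0.25
  }
  px <- sx + crest_s * nx
  py <- sy + crest_s * ny
  ## background statistics well away from the cell
  far <- !matrix(as.logical(EBImage::dilate(EBImage::Image(interior * 1),
                                            EBImage::makeBrush(9, "box")) > 0),
                 nr, nc)
  bg_med <- stats::median(membrane_image[far])
  bg_sd <- max(stats::mad(membrane_image[far]), 1e-9)
  well <- crest_val >= bg_med + contrast_mult * bg_sd
  if (!any(well))
    stop(structure(class = c("nanodwell_no_cell", "error", "condition"),
                   list(message = "no cell found: membrane ridge nowhere exceeds background",
                        call = sys.call())))
  structure(list(points = data.frame(x_nm = px * pitch_nm, y_nm = py * pitch_nm,
                                     nx = nx, ny = ny, well_defined = well),
                 interior = interior, pitch_nm = pitch_nm),
            class = "membrane_contour")
}

#' @export
print.membrane_contour <- function(x, ...) {
  cat("<membrane_contour>", nrow(x$points), "points,",
      sum(x$points$well_defined), "well defined\n")
  invisible(x)
}

#' Sample a two-channel intensity profile perpendicular to the membrane
#'
#' Samples both channels along a line through the contour point nearest
#' the particle, running from outside the cell toward the interior. The
#' membrane position is the first intensity peak of the membrane channel
#' encountered from the outside (interior peaks are vesicles and are
#' ignored), refined by a log-domain parabola, which is exact for the
#' Gaussian ridge cross-section. The particle position along the line is
#' the projection of its subpixel 2-d localization onto the profile axis
#' (the profile must still show a particle peak, whose refined position
#' is reported as `profile_peak_nm`). The signed separation `d_nm` is
#' positive when the particle lies past the membrane peak toward the
#' cell interior.
#'
#' @param membrane_image,particle_image the two channels of one frame.
#' @param contour a [extract_membrane_contour()] result for that frame.
#' @param particle_xy_nm length-2 vector, particle position (nm).
#' @param half_length_nm half-length of the sampled line (default 3000).
#' @param step_nm sampling step (default one third of a pixel).
#' @param prominence_frac minimum peak prominence, as a fraction of the
#'   channel's intensity range along the profile (default 0.2).
#' @return an object of class `intensity_profile`: list with `status`
#'   (`"ok"`, `"not_membrane_proximal"`, `"membrane_undefined"`,
#'   `"no_particle_peak"`), `s_nm` (positions along the line, 0 at the
#'   membrane peak, positive into the cell), `membrane`, `particle`
#'   (intensities), and `d_nm` (signed separation; NA unless status ok).
#' @export
sample_normal_profile <- function(membrane_image, particle_image, contour,
                                  particle_xy_nm, half_length_nm = 3000,
                                  step_nm = NULL, prominence_frac = 0.2) {
  stopifnot(inherits(contour, "membrane_contour"))
  pitch <- contour$pitch_nm
  if (is.null(step_nm)) step_nm <- pitch / 3
  pts <- contour$points
  ok <- pts$well_defined
  fail <- function(status) structure(list(status = status, s_nm = numeric(0),
                                          membrane = numeric(0),
                                          particle = numeric(0),
                                          d_nm = NA_real_),
                                     class = "intensity_profile")
  if (!any(ok)) return(fail("membrane_undefined"))
  d2 <- (pts$x_nm - particle_xy_nm[1])^2 + (pts$y_nm - particle_xy_nm[2])^2
  d2[!ok] <- Inf
  i <- which.min(d2)
  if (d2[i] > half_length_nm^2) return(fail("not_membrane_proximal"))
  ax <- pts$x_nm[i]; ay <- pts$y_nm[i]
  dirx <- -pts$nx[i]; diry <- -pts$ny[i]   # outside -> inside
  s <- seq(-half_length_nm, half_length_nm, by = step_nm)
  lx <- (ax + s * dirx) / pitch
  ly <- (ay + s * diry) / pitch
  mem <- bilinear_sample(membrane_image, lx, ly)
  par <- bilinear_sample(particle_image, lx, ly)
  valid <- !is.na(mem) & !is.na(par)
  s <- s[valid]; mem <- mem[valid]; par <- par[valid]
  if (length(s) < 5L) return(fail("membrane_undefined"))
  mpk <- find_peaks(mem, min_prominence = prominence_frac * diff(range(mem)))
  if (!length(mpk)) return(fail("membrane_undefined"))
  m1 <- mpk[1]                         # first peak from the outside
  ## log-domain parabola: exact for the Gaussian ridge cross-section and
  ## far less sensitive to the pixel lattice than a 3-point vertex
  s_mem <- refine_peak_gauss(s, mem, m1, hw = 2 * pitch)
  ppk <- find_peaks(par, min_prominence = prominence_frac * diff(range(par)))
  if (!length(ppk)) return(fail("no_particle_peak"))
  pbest <- ppk[which.max(par[ppk])]
  s_peak <- refine_peak_gauss(s, par, pbest, hw = 2 * pitch)
  ## the particle position itself is the best available estimate of its
  ## peak: project the subpixel localization onto the profile axis
  s_par <- (particle_xy_nm[1] - ax) * dirx + (particle_xy_nm[2] - ay) * diry
  structure(list(status = "ok", s_nm = s - s_mem, membrane = mem,
                 particle = par, membrane_peak_nm = s_mem,
                 particle_peak_nm = s_par, profile_peak_nm = s_peak,
                 d_nm = s_par - s_mem,
                 anchor_nm = c(ax, ay)),
            class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat("<intensity_profile>", x$status,
      if (!is.na(x$d_nm)) sprintf("d = %.1f nm", x$d_nm), "\n")
  invisible(x)
}

#' Mask of membrane positions common to two membrane frames
#'
#' For acquisitions in which the membrane is imaged only before and after
#' the particle time series, analysis must be restricted to regions where
#' the membrane did not move. Both frames are binarized (Otsu) and the
#' mask keeps the pixels of either membrane that lie within
#' `tolerance_px` of the other.
#'
#' @param membrane_before,membrane_after membrane-channel frames.
#' @param tolerance_px dilation tolerance in pixels (default 1).
#' @return logical matrix.
#' @export
overlap_mask <- function(membrane_before, membrane_after, tolerance_px = 1) {
  if (!all(dim(membrane_before) == dim(membrane_after)))
    stop_config("membrane frames must have the same shape")
  a <- binarize_membrane(membrane_before)
  b <- binarize_membrane(membrane_after)
  if (tolerance_px > 0) {
    brush <- EBImage::makeBrush(2 * tolerance_px + 1, "box")
    da <- matrix(as.logical(EBImage::dilate(EBImage::Image(a * 1), brush) > 0),
                 nrow(a), ncol(a))
    db <- matrix(as.logical(EBImage::dilate(EBImage::Image(b * 1), brush) > 0),
                 nrow(b), ncol(b))
  } else {
    da <- a; db <- b
  }
  (a & db) | (b & da)
}
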