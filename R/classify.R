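#' Classify a particle state from its signed membrane separation
#'
#' Applies the peak-separation rule: internalized when `d_nm` is at least
#' the threshold into the cell; adsorbed when the particle and membrane
#' peaks coincide within the adsorption window; free when the particle
#' lies outside the membrane by more than the window. Separations between
#' the window and the threshold (a particle in a not-yet-pinched-off
#' invagination) are conservatively kept as adsorbed. When no profile is
#' available (`d_nm = NA`, particle far from any membrane), the particle
#' is free if it is outside the cell and internalized if it lies deep in
#' the cell interior.
#'
#' @param d_nm signed separation (nm, positive into the cell); NA when the
#'   particle is not membrane-proximal.
#' @param config a [classifier_config()].
#' @param interior logical (recycled): is the particle's position inside
#'   the cell footprint? Used only when `d_nm` is NA.
#' @return character vector of states: `"free"`, `"adsorbed"`,
#'   `"internalized"`.
#' @examples
#' cc <- classifier_config(120)
#' classify_state(c(0, 300, -200, NA), cc, interior = FALSE)
#' @export
classify_state <- function(d_nm, config, interior = FALSE) {
  stopifnot(inherits(config, "classifier_config"))
  interior <- rep_len(interior, length(d_nm))
  out <- character(length(d_nm))
  absent <- is.na(d_nm)
  out[absent & interior] <- "internalized"
  out[absent & !interior] <- "free"
  out[!absent & d_nm >= config$threshold_nm] <- "internalized"
  out[!absent & d_nm <= -config$adsorption_window_nm] <- "free"
  out[out == ""] <- "adsorbed"
  out
}

## is a position (nm) inside the interior mask of a contour?
point_in_interior <- function(contour, x_nm, y_nm) {
  p <- contour$pitch_nm
  r <- round(y_nm / p); c <- round(x_nm / p)
  nr <- nrow(contour$interior); nc <- ncol(contour$interior)
  ok <- r >= 0 & r < nr & c >= 0 & c < nc
  res <- logical(length(x_nm))
  res[ok] <- contour$interior[cbind(r[ok] + 1, c[ok] + 1)]
  res
}

#' Per-frame state classification of tracked particles
#'
#' For every track point, samples the two-channel line profile
#' perpendicular to the membrane ([sample_normal_profile()]) and converts
#' the signed peak separation into a state ([classify_state()]). Points
#' whose local membrane is not well defined are labelled `"undefined"`.
#'
#' @param stack a [movie_stack()].
#' @param tracks output of [link_tracks()].
#' @param config a [classifier_config()].
#' @param half_length_nm,step_nm,prominence_frac profile parameters, see
#'   [sample_normal_profile()].
#' @param membrane_sampling `"per_frame"` (a contour per frame) or
#'   `"before_after"` (contour from the first membrane frame, analysis
#'   restricted to regions where first and last membrane frames overlap,
#'   as when the membrane is imaged only before and after the particle
#'   series).
#' @param overlap_tolerance_px tolerance for the before/after overlap
#'   mask.
#' @return data.frame: `track_id`, `frame`, `t_s`, `state`, `d_nm`,
#'   `membrane_defined`.
#' @export
classify_tracks <- function(stack, tracks, config,
                            half_length_nm = 3000, step_nm = NULL,
                            prominence_frac = 0.2,
                            membrane_sampling = c("per_frame", "before_after"),
                            overlap_tolerance_px = 1) {
  stopifnot(inherits(stack, "movie_stack"), inherits(config, "classifier_config"))
  membrane_sampling <- match.arg(membrane_sampling)
  d <- dim(stack$data)
  n_t <- d[1]; n_z <- d[2]
  mid_z <- (n_z + 1L) %/% 2L
  if (!nrow(tracks))
    return(data.frame(track_id = integer(0), frame = integer(0),
                      t_s = numeric(0), state = character(0),
                      d_nm = numeric(0), membrane_defined = logical(0)))

  mask <- NULL
  contour0 <- NULL
  if (membrane_sampling == "before_after") {
    before <- frame_image(stack, 0L, "membrane", mid_z)
    after <- frame_image(stack, n_t - 1L, "membrane", mid_z)
    mask <- overlap_mask(before, after, overlap_tolerance_px)
    contour0 <- extract_membrane_contour(before, stack$pitch_nm)
    ## keep only well-defined points whose pixel lies in the overlap mask
    pts <- contour0$points
    pr <- pmin(pmax(round(pts$y_nm / stack$pitch_nm), 0), nrow(mask) - 1)
    pc <- pmin(pmax(round(pts$x_nm / stack$pitch_nm), 0), ncol(mask) - 1)
    contour0$points$well_defined <- pts$well_defined &
      mask[cbind(pr + 1, pc + 1)]
  }

  out <- vector("list", n_t)
  for (t in sort(unique(tracks$frame))) {
    sel <- which(tracks$frame == t)
    contour <- if (membrane_sampling == "per_frame")
      tryCatch(extract_membrane_contour(frame_image(stack, t, "membrane", mid_z),
                                        stack$pitch_nm),
               nanodwell_no_cell = function(e) NULL)
    else contour0
    mem_img <- frame_image(stack, t, "membrane", mid_z)
    state <- character(length(sel))
    dnm <- rep(NA_real_, length(sel))
    mdef <- rep(TRUE, length(sel))
    for (k in seq_along(sel)) {
      i <- sel[k]
      if (is.null(contour)) { state[k] <- "undefined"; mdef[k] <- FALSE; next }
      zi <- if (n_z > 1L && "z_nm" %in% names(tracks)) {
        zp <- plane_z_from_stack(stack, n_z)
        which.min(abs(zp - tracks$z_nm[i]))
      } else mid_z
      par_img <- frame_image(stack, t, "particle", zi)
      prof <- sample_normal_profile(mem_img, par_img, contour,
                                    c(tracks$x_nm[i], tracks$y_nm[i]),
                                    half_length_nm, step_nm, prominence_frac)
      if (prof$status == "ok") {
        dnm[k] <- prof$d_nm
        state[k] <- classify_state(prof$d_nm, config)
      } else if (prof$status == "membrane_undefined") {
        state[k] <- "undefined"; mdef[k] <- FALSE
      } else {
        state[k] <- classify_state(NA_real_, config,
                                   interior = point_in_interior(
                                     contour, tracks$x_nm[i], tracks$y_nm[i]))
      }
    }
    out[[t + 1L]] <- data.frame(track_id = tracks$track_id[sel], frame = t,
                                t_s = t * stack$dt_s, state = state,
                                d_nm = dnm, membrane_defined = mdef)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$track_id, res$frame), , drop = FALSE]
  rownames(res) <- NULL
  res
}

plane_z_from_stack <- function(stack, n_z)
  (seq_len(n_z) - (n_z + 1) / 2) * stack$z_spacing_nm
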