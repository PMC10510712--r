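#' Merge per-plane detections of one time point into single objects
#'
#' In volumetric acquisitions the same particle appears in adjacent
#' z-planes. Detections of one time point closer laterally than
#' `z_merge_nm` are treated as one object; the merged lateral position is
#' the intensity-weighted mean over planes, and the axial position the
#' intensity-weighted mean of the plane coordinates.
#'
#' @param detections output of [detect_movie()] (columns `frame`, `z`,
#'   `x_nm`, `y_nm`, `intensity`, `quality`).
#' @param z_merge_nm lateral merge radius (nm).
#' @param z_spacing_nm plane spacing (nm).
#' @param n_z number of planes.
#' @return data.frame with one row per object: `frame`, `x_nm`, `y_nm`,
#'   `z_nm`, `intensity` (summed), `quality` (largest).
#' @export
merge_z_detections <- function(detections, z_merge_nm, z_spacing_nm, n_z) {
  if (!nrow(detections))
    return(data.frame(frame = integer(0), x_nm = numeric(0),
                      y_nm = numeric(0), z_nm = numeric(0),
                      intensity = numeric(0), quality = numeric(0)))
  zc <- (detections$z - (n_z - 1) / 2) * z_spacing_nm
  out <- lapply(split(seq_len(nrow(detections)), detections$frame), function(ix) {
    d <- detections[ix, , drop = FALSE]
    zd <- zc[ix]
    ord <- order(-d$quality)
    taken <- logical(nrow(d))
    rows <- list()
    for (i in ord) {
      if (taken[i]) next
      grp <- which(!taken & d$z != d$z[i] &
                     (d$x_nm - d$x_nm[i])^2 + (d$y_nm - d$y_nm[i])^2 <=
                     z_merge_nm^2)
      ## at most one partner per other plane: nearest one
      sel <- i
      for (zp in setdiff(unique(d$z[grp]), d$z[i])) {
        cand <- grp[d$z[grp] == zp]
        sel <- c(sel, cand[which.min((d$x_nm[cand] - d$x_nm[i])^2 +
                                       (d$y_nm[cand] - d$y_nm[i])^2)])
      }
      taken[sel] <- TRUE
      w <- d$intensity[sel]
      if (sum(w) <= 0) w <- rep(1, length(sel))
      rows[[length(rows) + 1L]] <- data.frame(
        frame = d$frame[i],
        x_nm = sum(d$x_nm[sel] * w) / sum(w),
        y_nm = sum(d$y_nm[sel] * w) / sum(w),
        z_nm = sum(zd[sel] * w) / sum(w),
        intensity = sum(d$intensity[sel]),
        quality = max(d$quality[sel]))
    }
    do.call(rbind, rows)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$frame, -res$quality), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Link detections into trajectories
#'
#' Frame-to-frame linking by optimal assignment: between consecutive
#' frames, the matching that minimizes the total squared displacement is
#' chosen among all matchings whose individual links are shorter than the
#' maximum linking distance. Unmatched detections start new tracks; a
#' track with no match terminates and never resumes (no gap closing), so
#' an object that moves farther than the cap between frames is split into
#' separate tracks.
#'
#' @param detections data.frame with columns `frame`, `x_nm`, `y_nm`
#'   (plus any extra columns, carried through). For volumetric data run
#'   [merge_z_detections()] first.
#' @param config a [tracker_config()].
#' @param dt_s frame interval; if given, a `t_s` column is added.
#' @return data.frame of track points: `track_id`, `frame`, `x_nm`,
#'   `y_nm`, extra detection columns, ordered by track then frame.
#' @examples
#' d <- data.frame(frame = rep(0:3, each = 1), x_nm = (0:3) * 100, y_nm = 0)
#' link_tracks(d, tracker_config(100))
#' @export
link_tracks <- function(detections, config = tracker_config(),
                        dt_s = NULL) {
  stopifnot(inherits(config, "tracker_config"))
  det <- as.data.frame(detections)
  if (!nrow(det)) {
    det$track_id <- integer(0)
    return(det)
  }
  det <- det[order(det$frame), , drop = FALSE]
  det$track_id <- NA_integer_
  cap <- config$max_link_nm
  frames <- sort(unique(det$frame))
  next_id <- 0L
  ## detections of the first frame (and any frame) with no predecessor
  ## start tracks; iterate over consecutive frame pairs
  idx_by_frame <- split(seq_len(nrow(det)), det$frame)
  start_new <- function(rows) {
    new_ids <- next_id + seq_along(rows)
    next_id <<- next_id + length(rows)
    det$track_id[rows] <<- new_ids
  }
  start_new(idx_by_frame[[1]])
  if (length(frames) > 1L) for (k in seq_len(length(frames) - 1L)) {
    fa <- frames[k]; fb <- frames[k + 1L]
    if (fb != fa + 1L) {  # dark gap: everything in fb starts new tracks
      start_new(idx_by_frame[[k + 1L]])
      next
    }
    ia <- idx_by_frame[[k]]
    ib <- idx_by_frame[[k + 1L]]
    m <- match_points(cbind(det$x_nm[ia], det$y_nm[ia]),
                      cbind(det$x_nm[ib], det$y_nm[ib]), cap)
    linked_b <- integer(0)
    for (r in seq_along(ia)) {
      if (!is.na(m[r])) {
        det$track_id[ib[m[r]]] <- det$track_id[ia[r]]
        linked_b <- c(linked_b, m[r])
      }
    }
    rest <- setdiff(seq_along(ib), linked_b)
    if (length(rest)) start_new(ib[rest])
  }
  det <- det[order(det$track_id, det$frame), , drop = FALSE]
  if (!is.null(dt_s)) det$t_s <- det$frame * dt_s
  rownames(det) <- NULL
  det
}

#' Per-step displacements of tracks
#'
#' @param tracks output of [link_tracks()].
#' @return data.frame with `track_id`, `frame` (of the later point) and
#'   `step_nm`, the 2-d displacement between consecutive frames.
#' @export
track_displacements <- function(tracks) {
  out <- lapply(split(tracks, tracks$track_id), function(tr) {
    if (nrow(tr) < 2L) return(NULL)
    tr <- tr[order(tr$frame), ]
    keep <- diff(tr$frame) == 1L
    if (!any(keep)) return(NULL)
    data.frame(track_id = tr$track_id[1],
               frame = tr$frame[-1][keep],
               step_nm = sqrt(diff(tr$x_nm)^2 + diff(tr$y_nm)^2)[keep])
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(track_id = integer(0), frame = integer(0),
                      step_nm = numeric(0))
  rownames(out) <- NULL
  out
}
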