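#' Match classified track points to simulator ground truth
#'
#' For every classified track point, finds the nearest ground-truth
#' particle position in the same frame (within `max_dist_nm`) and pairs
#' the predicted state with the true one. Points with no truth particle
#' nearby are dropped (they are spurious detections, reported in the
#' attribute `n_unmatched`).
#'
#' @param states output of [classify_tracks()].
#' @param tracks the tracks the states were computed from.
#' @param log the `ground_truth_log` of the simulation.
#' @param max_dist_nm maximum matching distance (nm).
#' @return data.frame with `track_id`, `frame`, `particle_id`,
#'   `state` (predicted) and `true_state`.
#' @export
match_states_to_truth <- function(states, tracks, log, max_dist_nm = 500) {
  key <- paste(tracks$track_id, tracks$frame)
  skey <- paste(states$track_id, states$frame)
  pos <- tracks[match(skey, key), c("x_nm", "y_nm")]
  out <- states
  out$particle_id <- NA_integer_
  out$true_state <- NA_character_
  tf <- split(log$frames, log$frames$frame)
  for (f in unique(states$frame)) {
    truth <- tf[[as.character(f)]]
    sel <- which(states$frame == f)
    if (is.null(truth) || !nrow(truth)) next
    tok <- is.finite(truth$x_nm)
    truth <- truth[tok, , drop = FALSE]
    if (!nrow(truth)) next
    for (k in sel) {
      d2 <- (truth$x_nm - pos$x_nm[k])^2 + (truth$y_nm - pos$y_nm[k])^2
      j <- which.min(d2)
      if (d2[j] <= max_dist_nm^2) {
        out$particle_id[k] <- truth$particle_id[j]
        out$true_state[k] <- truth$state[j]
      }
    }
  }
  res <- out[!is.na(out$true_state), , drop = FALSE]
  attr(res, "n_unmatched") <- sum(is.na(out$true_state))
  res
}

#' Per-frame state accuracy against ground truth
#'
#' @param run a `pipeline_run`.
#' @param max_dist_nm matching distance for [match_states_to_truth()].
#' @return list with `accuracy` (fraction of matched points whose
#'   predicted state equals the true one), `n_matched`, `n_unmatched`,
#'   and the `confusion` table.
#' @export
state_accuracy <- function(run, max_dist_nm = 500) {
  m <- match_states_to_truth(run$states, run$tracks, run$log, max_dist_nm)
  list(accuracy = mean(m$state == m$true_state),
       n_matched = nrow(m),
       n_unmatched = attr(m, "n_unmatched"),
       confusion = table(predicted = m$state, true = m$true_state))
}
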