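#' Extract membrane-residence events from per-frame state timelines
#'
#' A residence episode is a maximal run of consecutive `"adsorbed"`
#' frames within one track. Its terminal event is:
#' \describe{
#'   \item{internalization}{the run is followed by an `"internalized"`
#'     frame; the event time is from the first adsorbed frame to that
#'     first internalized frame (a single adsorbed frame suffices).}
#'   \item{desorption}{the run ends otherwise (the particle is next seen
#'     free, or vanishes) before the last movie frame; timed from first
#'     to last adsorbed frame, and only accepted when the run contains at
#'     least two successive adsorbed frames -- otherwise the episode is
#'     recorded as `sub_minimum`, since a single coincident frame cannot
#'     distinguish a membrane interaction from a particle merely passing
#'     near the membrane.}
#'   \item{censored}{the run reaches the final observed frame; no
#'     duration can be ascribed and the event is excluded from time
#'     statistics.}
#' }
#' A run whose preceding frame is `"internalized"` is not a new adsorption
#' episode (no return from the medium was observed) and is ignored.
#' Multiple episodes per track (desorption, then re-adsorption) are
#' allowed.
#'
#' @param states output of [classify_tracks()] (columns `track_id`,
#'   `frame`, `state`).
#' @param dt_s frame interval (s).
#' @param end_frame 0-based index of the last frame of the observation;
#'   default the largest frame present in `states`.
#' @param bridge_flickers if TRUE, a single non-adsorbed, non-internalized
#'   frame inside an otherwise adsorbed run is relabelled adsorbed before
#'   extraction (default FALSE: a flicker splits the episode).
#' @return data.frame with `track_id`, `type` (`"desorption"`,
#'   `"internalization"`, `"censored"`, `"sub_minimum"`), `first_frame`,
#'   `terminal_frame`, `t_start_s`, `duration_s` (NA for censored).
#' @examples
#' st <- data.frame(track_id = 1, frame = 0:2,
#'                  state = c("free", "adsorbed", "internalized"))
#' extract_events(st, dt_s = 1.25)
#' @export
extract_events <- function(states, dt_s, end_frame = NULL,
                           bridge_flickers = FALSE) {
  check_number(dt_s, "dt_s", min = 0, strict = TRUE)
  if (is.null(end_frame)) end_frame <- max(states$frame, -1L)
  empty <- data.frame(track_id = integer(0), type = character(0),
                      first_frame = integer(0), terminal_frame = integer(0),
                      t_start_s = numeric(0), duration_s = numeric(0))
  if (!nrow(states)) return(empty)
  out <- lapply(split(states, states$track_id), function(tr) {
    if (is.unsorted(tr$frame, strictly = TRUE))
      stop_config("frames must be strictly increasing within a track")
    st <- tr$state
    n <- length(st)
    if (bridge_flickers && n >= 3L) {
      flick <- which(st[2:(n - 1)] != "adsorbed" &
                       st[2:(n - 1)] != "internalized" &
                       st[1:(n - 2)] == "adsorbed" &
                       st[3:n] == "adsorbed") + 1L
      st[flick] <- "adsorbed"
    }
    ads <- st == "adsorbed"
    if (!any(ads)) return(NULL)
    r <- rle(ads)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    evs <- lapply(runs, function(k) {
      i1 <- starts[k]; i2 <- ends[k]
      ## ignore runs that continue an internalized residence
      if (i1 > 1L && st[i1 - 1L] == "internalized") return(NULL)
      f1 <- tr$frame[i1]; f2 <- tr$frame[i2]
      if (i2 < n && st[i2 + 1L] == "internalized") {
        fint <- tr$frame[i2 + 1L]
        return(data.frame(track_id = tr$track_id[1], type = "internalization",
                          first_frame = f1, terminal_frame = fint,
                          t_start_s = f1 * dt_s,
                          duration_s = (fint - f1) * dt_s))
      }
      if (i2 == n && f2 >= end_frame)
        return(data.frame(track_id = tr$track_id[1], type = "censored",
                          first_frame = f1, terminal_frame = f2,
                          t_start_s = f1 * dt_s, duration_s = NA_real_))
      type <- if (f2 - f1 + 1L >= 2L) "desorption" else "sub_minimum"
      data.frame(track_id = tr$track_id[1], type = type,
                 first_frame = f1, terminal_frame = f2,
                 t_start_s = f1 * dt_s, duration_s = (f2 - f1) * dt_s)
    })
    do.call(rbind, evs)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}
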