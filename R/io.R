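#' Write a simulated movie, its ground truth and its configuration to disk
#'
#' The movie is stored as a multi-page 16-bit TIFF (page order T, Z, C:
#' slowest to fastest), the ground-truth frame log as CSV, and the
#' configuration plus axis metadata as a JSON sidecar. Reading the fixture
#' back reproduces the intensity array bit-exactly (intensities are
#' integer camera counts).
#'
#' @param stack a [movie_stack()] with integer intensities in
#'   `[0, 65535]` (the digitized output of [render_movie()]).
#' @param log the matching `ground_truth_log` (or NULL to skip).
#' @param dir destination directory.
#' @param name base name for the three files.
#' @param overwrite overwrite an existing fixture (default FALSE).
#' @return invisibly, the paths written.
#' @export
write_fixture <- function(stack, log, dir, name = "movie", overwrite = FALSE) {
  stopifnot(inherits(stack, "movie_stack"))
  arr <- stack$data
  if (any(arr != round(arr)) || any(arr > 65535))
    stop_config("movie intensities must be integer counts in [0, 65535]; ",
                "render with noise/digitization enabled")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(name, c(".tif", "_truth.csv", ".json")))
  if (!overwrite && any(file.exists(paths)))
    stop_config("fixture files already exist in ", dir,
                " (use overwrite = TRUE)")
  d <- dim(arr)
  pages <- vector("list", d[1] * d[2] * d[3])
  i <- 0L
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) for (ch in seq_len(d[3])) {
    i <- i + 1L
    pages[[i]] <- arr[t, z, ch, , ] / 65535
  }
  tiff::writeTIFF(pages, paths[1], bits.per.sample = 16L, compression = "none")
  if (!is.null(log)) {
    utils::write.csv(log$frames, paths[2], row.names = FALSE)
  } else {
    paths <- paths[-2]
  }
  meta <- list(axes = "TZCYX",
               dim = as.list(stats::setNames(as.integer(d),
                                             c("T", "Z", "C", "Y", "X"))),
               channels = list(membrane = 1, particle = 2),
               pitch_nm = stack$pitch_nm, z_spacing_nm = stack$z_spacing_nm,
               dt_s = stack$dt_s,
               config = if (!is.null(log)) unclass(log$config) else NULL)
  jsonlite::write_json(meta, paths[length(paths)], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(paths)
}

#' Read a movie fixture written by [write_fixture()]
#'
#' @param dir fixture directory.
#' @param name base name used when writing.
#' @return a list with elements `stack` (a [movie_stack()]), `truth`
#'   (the ground-truth frame data.frame, or NULL), and `config`
#'   (the stored configuration list).
#' @export
read_fixture <- function(dir, name = "movie") {
  tif <- file.path(dir, paste0(name, ".tif"))
  sidecar <- file.path(dir, paste0(name, ".json"))
  if (!file.exists(sidecar))
    stop_config("config sidecar absent: ", sidecar)
  if (!file.exists(tif)) stop_config("movie absent: ", tif)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  d <- unlist(meta$dim)[c("T", "Z", "C", "Y", "X")]
  pages <- tiff::readTIFF(tif, all = TRUE)
  if (length(pages) != prod(d[1:3]))
    stop_config("TIFF page count does not match sidecar dimensions")
  arr <- array(0, dim = unname(d))
  i <- 0L
  for (t in seq_len(d[[1]])) for (z in seq_len(d[[2]])) for (ch in seq_len(d[[3]])) {
    i <- i + 1L
    arr[t, z, ch, , ] <- round(pages[[i]] * 65535)
  }
  truth_path <- file.path(dir, paste0(name, "_truth.csv"))
  truth <- if (file.exists(truth_path))
    utils::read.csv(truth_path, stringsAsFactors = FALSE) else NULL
  stack <- movie_stack(arr, pitch_nm = as.numeric(meta$pitch_nm),
                       z_spacing_nm = as.numeric(meta$z_spacing_nm),
                       dt_s = as.numeric(meta$dt_s))
  list(stack = stack, truth = truth, config = meta$config)
}
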