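#' @keywords internal
"_PACKAGE"

## lightweight argument checks used across the package

stop_config <- function(...) {
  stop(structure(class = c("nanodwell_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_number <- function(x, name, min = -Inf, strict = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_config(name, " must be a single number")
  if (finite && !is.finite(x)) stop_config(name, " must be finite")
  if (strict && x <= min) stop_config(name, " must be > ", min)
  if (!strict && x < min) stop_config(name, " must be >= ", min)
  invisible(x)
}

## bilinear interpolation of an image (matrix, rows = y, cols = x) at
## continuous pixel coordinates (0-based, origin at first pixel centre).
## Points outside the image return NA.
bilinear_sample <- function(img, x_px, y_px) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- floor(x_px); y0 <- floor(y_px)
  fx <- x_px - x0; fy <- y_px - y0
  ok <- x0 >= 0 & y0 >= 0 & x0 <= nc - 1 & y0 <= nr - 1 &
    (x0 + 1 <= nc - 1 | fx == 0) & (y0 + 1 <= nr - 1 | fy == 0)
  out <- rep(NA_real_, length(x_px))
  if (!any(ok)) return(out)
  x0k <- x0[ok]; y0k <- y0[ok]; fxk <- fx[ok]; fyk <- fy[ok]
  x1k <- pmin(x0k + 1, nc - 1); y1k <- pmin(y0k + 1, nr - 1)
  i00 <- (x0k) * nr + y0k + 1   # column-major index for [y0+1, x0+1]
  i01 <- (x1k) * nr + y0k + 1
  i10 <- (x0k) * nr + y1k + 1
  i11 <- (x1k) * nr + y1k + 1
  out[ok] <- img[i00] * (1 - fxk) * (1 - fyk) + img[i01] * fxk * (1 - fyk) +
    img[i10] * (1 - fxk) * fyk + img[i11] * fxk * fyk
  out
}

## local maxima of a 1-d signal with a minimum topographic prominence.
## Returns integer indices of retained peaks (strict local maxima; plateaus
## are represented by their first sample).
find_peaks <- function(y, min_prominence = 0) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  is_peak <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  if (!length(is_peak)) return(integer(0))
  prom <- vapply(is_peak, function(i) {
    h <- y[i]
    ## walk left until a higher sample; key saddle is the minimum passed
    left <- y[seq_len(i - 1)]
    higher_l <- which(left > h)
    lmin <- if (length(higher_l)) min(y[(max(higher_l) + 1):(i - 1)], h) else min(left, h)
    right <- y[(i + 1):n]
    higher_r <- which(right > h)
    rmin <- if (length(higher_r)) min(y[(i + 1):(i + min(higher_r) - 1)], h) else min(right, h)
    h - max(lmin, rmin)
  }, numeric(1))
  is_peak[prom >= min_prominence]
}

## Sub-sample refinement of a Gaussian-shaped peak at sample index i of a
## signal y(s): least-squares parabola in log intensity (exact for a
## Gaussian) over the samples within half-width hw of the peak. Returns a
## position in the units of s; falls back to 3-point parabolic refinement
## when the window is degenerate.
refine_peak_gauss <- function(s, y, i, hw) {
  fallback <- s[1] + (refine_peak(y, i) - 1) * (s[2] - s[1])
  sel <- which(abs(s - s[i]) <= hw & y > 0.05 * y[i])
  if (length(sel) < 5 || any(y[sel] <= 0)) return(fallback)
  X <- cbind(1, s[sel], s[sel]^2)
  co <- tryCatch(stats::lm.fit(X, log(y[sel]))$coefficients,
                 error = function(e) c(NA, NA, NA))
  if (!is.finite(co[3]) || co[3] >= 0) return(fallback)
  v <- -co[2] / (2 * co[3])
  if (abs(v - s[i]) > hw) fallback else v
}

## parabolic sub-sample refinement of a local maximum at index i
refine_peak <- function(y, i) {
  n <- length(y)
  if (i <= 1L || i >= n) return(as.numeric(i))
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (denom >= 0) return(as.numeric(i))
  i + 0.5 * (y[i - 1] - y[i + 1]) / denom
}
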