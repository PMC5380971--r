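# Otsu thresholding helpers. The histogram search itself is EBImage's;
# these wrappers handle arbitrary intensity ranges and the windowed
# ("adaptive") variant with bilinear interpolation between window centres.

.otsu_value <- function(v, levels = 256L) {
  v <- v[is.finite(v)]
  if (length(v) < 2) return(Inf)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(Inf)           # flat region: nothing is foreground
  m <- matrix((v - lo) / (hi - lo), ncol = 1)
  thr <- EBImage::otsu(m, range = c(0, 1), levels = levels)
  lo + thr * (hi - lo)
}

#' Global Otsu threshold of an image
#'
#' @param image numeric matrix (any intensity range).
#' @return The scalar threshold; pixels strictly above it are foreground.
#' @export
otsu_global <- function(image) {
  .otsu_value(as.numeric(image))
}

#' Adaptive (windowed) Otsu threshold map
#'
#' Computes an Otsu threshold per non-overlapping window of
#' \code{window_px} pixels and bilinearly interpolates the per-window
#' values between window centres, yielding a full-resolution threshold
#' surface. Window thresholds are clamped to
#' \code{[0.7, 1.5] x} the global Otsu threshold so that empty windows
#' (background only) do not produce spurious foreground — the standard
#' safeguard for windowed Otsu in cell-segmentation pipelines.
#'
#' @param image numeric matrix.
#' @param window_px window edge length in pixels.
#' @param clamp length-2 multiplier range applied against the global
#'   threshold, or \code{NULL} to disable clamping.
#' @return A matrix of thresholds, same size as \code{image}.
#' @export
otsu_adaptive <- function(image, window_px, clamp = c(0.7, 1.5)) {
  stopifnot(is.matrix(image), window_px >= 2)
  nr <- nrow(image); nc <- ncol(image)
  w <- as.integer(min(window_px, nr, nc))
  rb <- split(seq_len(nr), ceiling(seq_len(nr) / w))
  cb <- split(seq_len(nc), ceiling(seq_len(nc) / w))
  thr <- matrix(0, length(rb), length(cb))
  for (i in seq_along(rb))
    for (j in seq_along(cb))
      thr[i, j] <- .otsu_value(image[rb[[i]], cb[[j]]])
  g <- .otsu_value(as.numeric(image))
  if (!is.null(clamp) && is.finite(g)) {
    thr[!is.finite(thr)] <- g * clamp[2]
    thr <- pmin(pmax(thr, g * clamp[1]), g * clamp[2])
  } else {
    thr[!is.finite(thr)] <- max(image) + 1   # flat windows: no foreground
  }
  rc <- vapply(rb, function(ix) mean(range(ix)), numeric(1))
  cc <- vapply(cb, function(ix) mean(range(ix)), numeric(1))
  .bilinear_expand(thr, rc, cc, nr, nc)
}

# expand a coarse grid of values (at centres rc x cc) to full resolution by
# separable linear interpolation with constant extrapolation at the borders
.bilinear_expand <- function(vals, rc, cc, nr, nc) {
  interp1 <- function(x, y, xout) {
    if (length(x) == 1) return(rep(y, length(xout)))
    approx(x, y, xout = xout, rule = 2)$y
  }
  tmp <- matrix(0, nr, length(cc))
  for (j in seq_along(cc)) tmp[, j] <- interp1(rc, vals[, j], seq_len(nr))
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) out[i, ] <- interp1(cc, tmp[i, ], seq_len(nc))
  out
}
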