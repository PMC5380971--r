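# Undecimated a-trous wavelet transform with the B3-spline generating
# kernel. Detail planes are differences of successive smoothings, so the
# decomposition reconstructs the input exactly (telescoping sum) for any
# boundary handling; boundaries use mirror reflection.

.reflect_index <- function(idx, n) {
  # reflect out-of-range indices at the borders (1 and n), repeatedly for
  # steps larger than the image
  while (any(idx < 1L | idx > n)) {
    idx <- ifelse(idx < 1L, 2L - idx, idx)
    idx <- ifelse(idx > n, 2L * n - idx, idx)
  }
  idx
}

.b3_taps <- c(1, 4, 6, 4, 1) / 16

.atrous_smooth <- function(m, step) {
  nr <- nrow(m); nc <- ncol(m)
  offs <- c(-2L, -1L, 0L, 1L, 2L) * as.integer(step)
  out <- matrix(0, nr, nc)
  for (i in 1:5) {                        # rows
    idx <- .reflect_index(seq_len(nr) + offs[i], nr)
    out <- out + .b3_taps[i] * m[idx, , drop = FALSE]
  }
  m2 <- out
  out <- matrix(0, nr, nc)
  for (i in 1:5) {                        # columns
    idx <- .reflect_index(seq_len(nc) + offs[i], nc)
    out <- out + .b3_taps[i] * m2[, idx, drop = FALSE]
  }
  out
}

#' A-trous B3-spline wavelet decomposition
#'
#' Undecimated multiscale decomposition used for spot detection. Smoothing
#' level \emph{j} convolves with the separable 1D kernel
#' \code{(1/16, 1/4, 3/8, 1/4, 1/16)} whose taps are spaced \code{2^(j-1)}
#' pixels apart (mirror boundary). Detail plane \emph{j} is
#' \code{smooth(j-1) - smooth(j)}; the residual is the last smoothing. The
#' sum of all detail planes plus the residual equals the input exactly.
#' Low detail planes respond to small, diffraction-limited spots; higher
#' planes to larger structures.
#'
#' @param image numeric matrix.
#' @param n_levels number of detail planes (>= 1); must not exceed
#'   \code{floor(log2(min(dim(image))))} so the widest kernel still fits
#'   the image.
#' @return A list with \code{detail} (list of \code{n_levels} matrices) and
#'   \code{residual} (matrix).
#' @examples
#' x <- matrix(rnorm(64 * 64), 64, 64)
#' w <- atrous_decompose(x, 3)
#' max(abs(Reduce(`+`, w$detail) + w$residual - x)) # ~ 1e-16
#' @export
atrous_decompose <- function(image, n_levels) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (n_levels < 1) stop("n_levels must be >= 1")
  if (n_levels > floor(log2(min(dim(image)))))
    stop("n_levels = ", n_levels, " exceeds log2 of the smallest image ",
         "dimension (", min(dim(image)), " px)")
  detail <- vector("list", n_levels)
  prev <- image
  for (j in seq_len(n_levels)) {
    sm <- .atrous_smooth(prev, 2^(j - 1))
    detail[[j]] <- prev - sm
    prev <- sm
  }
  list(detail = detail, residual = prev)
}
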