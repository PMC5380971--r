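#' Calibrated multi-channel field image
#'
#' Container for a multi-channel 2D image, z-stack or time-lapse together
#' with its physical calibration. Channels are named matrices (2D) or
#' row x col x z arrays (stacks); all channels must share spatial
#' dimensions. Coordinates throughout the package are 1-based
#' \code{(row, col)} with the origin at the top-left pixel; areas are
#' reported in um^2 as \code{pixel_count * pixel_size_um^2}.
#'
#' @param channels named list of numeric matrices or 3D arrays.
#' @param pixel_size_um lateral pixel size in um/px. The default 0.133
#'   corresponds to the calibration at which a 2-pixel boundary gap equals
#'   0.266 um.
#' @param z_step_um axial spacing in um (z-stacks only), or \code{NULL}.
#' @param frame_interval_s frame interval in seconds (time-lapse only), or
#'   \code{NULL}.
#' @return An object of class \code{field_image}.
#' @export
field_image <- function(channels, pixel_size_um = 0.133, z_step_um = NULL,
                        frame_interval_s = NULL) {
  stopifnot(is.list(channels), length(channels) >= 1)
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("all channels must be named")
  dims <- lapply(channels, function(ch) dim(ch)[1:2])
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("all channels must share identical spatial dimensions")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be a single positive number")
  structure(list(channels = channels,
                 pixel_size_um = pixel_size_um,
                 z_step_um = z_step_um,
                 frame_interval_s = frame_interval_s),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("<field_image> ", paste(d, collapse = " x "),
      " | channels: ", paste(names(x$channels), collapse = ", "),
      " | ", x$pixel_size_um, " um/px\n", sep = "")
  invisible(x)
}

#' Read a multi-channel TIFF into a field image
#'
#' Reads a (multi-page) TIFF and maps its pages onto named channels. For a
#' z-stack, pages are assumed channel-interleaved by plane
#' (c1z1, c2z1, ..., c1z2, ...) when \code{n_z > 1}.
#'
#' @param path path to a TIFF file.
#' @param channel_names character vector naming the channels in page order.
#' @param n_z number of z-planes per channel (default 1).
#' @param pixel_size_um,z_step_um,frame_interval_s calibration, as in
#'   \code{\link{field_image}}.
#' @return A \code{\link{field_image}}.
#' @export
read_field <- function(path, channel_names, n_z = 1, pixel_size_um = 0.133,
                       z_step_um = NULL, frame_interval_s = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = FALSE),
                    error = function(e) stop("unreadable TIFF '", path, "': ",
                                             conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  n_ch <- length(channel_names)
  if (length(pages) != n_ch * n_z)
    stop("channel-count mismatch in '", path, "': expected ", n_ch * n_z,
         " pages (", n_ch, " channels x ", n_z, " planes), found ",
         length(pages))
  chans <- vector("list", n_ch)
  names(chans) <- channel_names
  # snap to the storage grid: recover the exact 32-bit integer sample,
  # then rescale to counts (exact in binary arithmetic)
  pages <- lapply(pages, function(p) round(p * (2^32 - 1)) / 65536)
  for (ci in seq_len(n_ch)) {
    if (n_z == 1) {
      chans[[ci]] <- pages[[ci]]
    } else {
      planes <- pages[seq(ci, by = n_ch, length.out = n_z)]
      chans[[ci]] <- array(unlist(planes), dim = c(dim(planes[[1]]), n_z))
    }
  }
  field_image(chans, pixel_size_um = pixel_size_um, z_step_um = z_step_um,
              frame_interval_s = frame_interval_s)
}

# Fixed intensity quantisation of the package's 32-bit TIFFs: intensities
# are stored on a 1/65536-count grid, which makes integer counts up to
# 65535 round-trip exactly and quantises fractional values to 2^-16.
.tiff_unit <- 65536 / (2^32 - 1)

#' Write a field image to a multi-page TIFF
#'
#' Channels (and z-planes, channel-interleaved) are written as 32-bit
#' pages on a fixed 1/65536-count grid, so integer intensities up to
#' 65535 round-trip losslessly (fractional intensities are quantised to
#' 2^-16 of a count).
#'
#' @param x a \code{\link{field_image}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_field <- function(x, path) {
  stopifnot(inherits(x, "field_image"))
  pages <- list()
  n_z <- if (length(dim(x$channels[[1]])) == 3) dim(x$channels[[1]])[3] else 1
  for (z in seq_len(n_z))
    for (ch in x$channels)
      pages[[length(pages) + 1]] <-
        (if (length(dim(ch)) == 3) ch[, , z] else ch) * .tiff_unit
  if (any(vapply(pages, function(p) max(p) > 1 || min(p) < 0, logical(1))))
    stop("intensities must lie in [0, 65535] for TIFF storage")
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  invisible(path)
}

#' Write or read an integer label map as TIFF
#'
#' Label maps use 0 for background and positive integers for objects;
#' they are stored as 32-bit TIFF on the package's fixed intensity grid,
#' exact for labels up to 65535.
#'
#' @param labels integer matrix.
#' @param path file path.
#' @return \code{write_label_map}: \code{path} invisibly;
#'   \code{read_label_map}: an integer matrix.
#' @export
write_label_map <- function(labels, path) {
  stopifnot(max(labels) <= 65535, min(labels) >= 0)
  tiff::writeTIFF(matrix(as.numeric(labels) * .tiff_unit,
                         nrow(labels), ncol(labels)),
                  path, bits.per.sample = 32, reduce = FALSE)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m / .tiff_unit)), nrow(m), ncol(m))
}

#' Maximum-intensity projection of a z-stack
#'
#' Per-pixel maximum across z. A single 2D plane is returned unchanged, so
#' the operation is idempotent.
#'
#' @param stack a 2D matrix or a row x col x z array with at least one plane.
#' @return A 2D matrix.
#' @export
max_project <- function(stack) {
  d <- dim(stack)
  if (is.null(d) || length(d) < 2 || any(d == 0))
    stop("stack must be a non-empty 2D or 3D array")
  if (length(d) == 2) return(stack)
  if (length(d) != 3) stop("stack must be 2D or 3D")
  out <- stack[, , 1]
  for (z in seq_len(d[3])[-1]) out <- pmax(out, stack[, , z])
  out
}

#' Write measurement records to CSV
#'
#' Writes one row per object with a stable column order and full numeric
#' precision (values are serialised with \code{format(..., digits = 17)}
#' via R's default CSV writer), so identical inputs yield byte-identical
#' files.
#'
#' @param records a data.frame (possibly with zero rows).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_measurements <- function(records, path) {
  stopifnot(is.data.frame(records))
  rec <- records
  for (j in seq_along(rec))
    if (is.numeric(rec[[j]]) && !is.integer(rec[[j]]))
      rec[[j]] <- vapply(rec[[j]], function(v)
        if (is.na(v)) NA_character_ else format(v, digits = 17),
        character(1))
  write.csv(rec, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read a measurements CSV written by \code{write_measurements}
#'
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_measurements <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
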