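#' Build droplet records from a label map
#'
#' Converts a labelled LD image into a set of per-droplet records carrying
#' the mask pixels, boundary pixels, calibrated area, equivalent diameter,
#' centroid, mean intensity and (optionally) the owning cell. The owning
#' cell is the cell label at the droplet's centroid; droplets whose
#' centroid falls outside every cell get \code{cell_id = NA} and are
#' excluded from per-cell statistics.
#'
#' @param labels integer label map (0 background); each label must be one
#'   8-connected component.
#' @param intensity numeric matrix of the LD channel (same size), used for
#'   mean intensities; may be \code{NULL}.
#' @param pixel_size_um pixel size in um/px.
#' @param cells optional cell label map for ownership assignment.
#' @return An object of class \code{ld_droplets}: a list with
#'   \code{table} (one row per droplet: \code{id}, \code{area_um2},
#'   \code{equivalent_diameter_um}, \code{centroid_row}, \code{centroid_col},
#'   \code{mean_intensity}, \code{cell_id}), \code{px} / \code{boundary}
#'   (lists of pixel-coordinate matrices), \code{labels} and
#'   \code{pixel_size_um}.
#' @export
droplet_records <- function(labels, intensity = NULL, pixel_size_um,
                            cells = NULL) {
  stopifnot(is.matrix(labels))
  if (missing(pixel_size_um) || is.null(pixel_size_um))
    stop("missing calibration: pixel_size_um is required")
  bnd <- .boundary_mask(labels)
  idx <- which(labels > 0L)
  if (length(idx) == 0) return(.empty_droplets(labels, pixel_size_um))
  lab <- as.integer(labels[idx])
  coord <- arrayInd(idx, dim(labels))
  ord <- order(lab)
  lab <- lab[ord]; coord <- coord[ord, , drop = FALSE]; idx <- idx[ord]
  ids <- unique(lab)
  grp <- split(seq_along(lab), lab)
  px <- vector("list", length(ids))
  boundary <- vector("list", length(ids))
  n <- length(ids)
  tab <- data.frame(id = ids,
                    area_um2 = numeric(n),
                    equivalent_diameter_um = numeric(n),
                    centroid_row = numeric(n), centroid_col = numeric(n),
                    mean_intensity = rep(NA_real_, n),
                    cell_id = rep(NA_integer_, n))
  for (k in seq_len(n)) {
    sel <- grp[[k]]
    p <- coord[sel, , drop = FALSE]
    colnames(p) <- c("row", "col")
    px[[k]] <- p
    boundary[[k]] <- p[bnd[idx[sel]], , drop = FALSE]
    a_um2 <- nrow(p) * pixel_size_um^2
    tab$area_um2[k] <- a_um2
    tab$equivalent_diameter_um[k] <- 2 * sqrt(a_um2 / pi)
    tab$centroid_row[k] <- mean(p[, 1])
    tab$centroid_col[k] <- mean(p[, 2])
    if (!is.null(intensity)) tab$mean_intensity[k] <- mean(intensity[p])
    if (!is.null(cells)) {
      cid <- cells[round(tab$centroid_row[k]), round(tab$centroid_col[k])]
      tab$cell_id[k] <- if (cid > 0L) as.integer(cid) else NA_integer_
    }
  }
  structure(list(table = tab, px = px, boundary = boundary,
                 labels = labels, pixel_size_um = pixel_size_um),
            class = "ld_droplets")
}

.empty_droplets <- function(labels, pixel_size_um) {
  structure(list(table = data.frame(id = integer(0), area_um2 = numeric(0),
                                    equivalent_diameter_um = numeric(0),
                                    centroid_row = numeric(0),
                                    centroid_col = numeric(0),
                                    mean_intensity = numeric(0),
                                    cell_id = integer(0)),
                 px = list(), boundary = list(), labels = labels,
                 pixel_size_um = pixel_size_um),
            class = "ld_droplets")
}

#' @export
print.ld_droplets <- function(x, ...) {
  cat("<ld_droplets> ", nrow(x$table), " droplets | ",
      sum(!is.na(x$table$cell_id)), " assigned to cells | ",
      x$pixel_size_um, " um/px\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.ld_droplets <- function(x, ...) x$table

# number of droplets
.n_droplets <- function(droplets) nrow(droplets$table)

# rebuild an ld_droplets object from an explicit list of pixel matrices
.droplets_from_px <- function(px_list, dims, intensity, pixel_size_um,
                              cells = NULL) {
  labels <- matrix(0L, dims[1], dims[2])
  for (k in seq_along(px_list)) labels[px_list[[k]]] <- k
  droplet_records(labels, intensity, pixel_size_um, cells)
}
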