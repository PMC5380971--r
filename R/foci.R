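#' Foci detection and assignment parameters
#'
#' Marker patches ("foci") are diffraction-limited local maxima of an
#' immunostain or fluorescent-fusion channel. The minimum intensity a
#' patch must reach is a preset criterion; it can be given either as an
#' absolute value or as a percentile of the whole stack (the default,
#' 99.5, emulates a "preset minimum intensity" chosen on the bright tail
#' of the marker signal).
#'
#' @param min_intensity either a number (absolute threshold) or a list
#'   \code{list(percentile = p)}.
#' @param min_ld_diameter_um only LDs with equivalent diameter at or above
#'   this are eligible for patch counting (default 1 um).
#' @param assign_radius_um maximum distance from a focus to an LD boundary
#'   for assignment (default 0.3 um, on the order of the lateral
#'   resolution).
#' @param z_merge_um maxima in adjacent sections closer than this axially
#'   (and within \code{assign_radius_um} laterally) are one focus.
#' @return A list of class \code{foci_params}.
#' @export
foci_params <- function(min_intensity = list(percentile = 99.5),
                        min_ld_diameter_um = 1.0,
                        assign_radius_um = 0.3,
                        z_merge_um = 0.5) {
  if (is.list(min_intensity)) {
    stopifnot(!is.null(min_intensity$percentile),
              min_intensity$percentile > 0, min_intensity$percentile < 100)
  } else {
    stopifnot(is.numeric(min_intensity), length(min_intensity) == 1)
  }
  stopifnot(min_ld_diameter_um > 0, assign_radius_um > 0, z_merge_um > 0)
  structure(list(min_intensity = min_intensity,
                 min_ld_diameter_um = min_ld_diameter_um,
                 assign_radius_um = assign_radius_um,
                 z_merge_um = z_merge_um),
            class = "foci_params")
}

#' Detect marker foci in a z-stack
#'
#' Finds per-section 2D local maxima above the preset minimum intensity,
#' then merges maxima that appear in nearby sections (within
#' \code{z_merge_um} axially and \code{assign_radius_um} laterally) into
#' a single focus at its brightest section, making the per-section
#' inspection of a stack explicit and deduplicated.
#'
#' @param marker_stack 3D array (row, col, z) or a 2D matrix (treated as
#'   a single-section stack).
#' @param params a \code{\link{foci_params}}.
#' @param pixel_size_um lateral calibration (um/px).
#' @param z_step_um axial step (um); default 0.25.
#' @return A data.frame with one row per focus: \code{id}, \code{z},
#'   \code{row}, \code{col}, \code{peak_intensity}.
#' @export
detect_foci <- function(marker_stack, params = foci_params(),
                        pixel_size_um = 0.133, z_step_um = 0.25) {
  if (is.matrix(marker_stack))
    marker_stack <- array(marker_stack, dim = c(dim(marker_stack), 1L))
  stopifnot(length(dim(marker_stack)) == 3)
  thr <- if (is.list(params$min_intensity)) {
    # percentile preset, floored at a robust background band (so a stack
    # with very sparse signal cannot place the cut inside noise) and at a
    # fraction of the dynamic range (so out-of-focus tails of bright
    # patches are not counted as patches of their own)
    med <- median(marker_stack)
    max(quantile(marker_stack, params$min_intensity$percentile / 100,
                 names = FALSE),
        med + 3 * mad(marker_stack),
        med + 0.15 * (max(marker_stack) - med))
  } else params$min_intensity
  n_z <- dim(marker_stack)[3]
  cand <- list()
  for (z in seq_len(n_z)) {
    mx <- .local_maxima(marker_stack[, , z], thr)
    if (nrow(mx))
      cand[[length(cand) + 1L]] <-
        data.frame(z = z, row = mx[, 1], col = mx[, 2],
                   peak_intensity = marker_stack[, , z][mx])
  }
  if (length(cand) == 0)
    return(data.frame(id = integer(0), z = integer(0), row = numeric(0),
                      col = numeric(0), peak_intensity = numeric(0)))
  cand <- do.call(rbind, cand)
  # merge across sections: same focus if within lateral and axial reach;
  # keep the brightest section. Process brightest-first so every focus
  # claims its neighbourhood deterministically.
  ord <- order(-cand$peak_intensity, cand$z, cand$row, cand$col)
  cand <- cand[ord, ]
  lat_px <- params$assign_radius_um / pixel_size_um
  z_sec <- max(1, params$z_merge_um / z_step_um)
  taken <- rep(FALSE, nrow(cand))
  keep <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (taken[i]) next
    close_by <- !taken &
      abs(cand$z - cand$z[i]) <= z_sec + 1e-9 &
      sqrt((cand$row - cand$row[i])^2 + (cand$col - cand$col[i])^2) <=
        lat_px + 1e-9
    taken[close_by] <- TRUE
    keep <- c(keep, i)
  }
  out <- cand[keep, ]
  out <- out[order(out$z, out$row, out$col), ]
  out$id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("id", "z", "row", "col", "peak_intensity")]
}

#' Assign foci to lipid droplets and flag contact-site patches
#'
#' Only LDs whose equivalent diameter is at least
#' \code{min_ld_diameter_um} are eligible. A focus is assigned to every
#' eligible LD whose boundary lies within \code{assign_radius_um}; when
#' three or more qualify it is assigned to the two nearest (ties broken
#' by lower LD id). A focus assigned to exactly two LDs whose mutual
#' boundary gap is at most \code{cluster_threshold_px} is flagged as a
#' patch at an LD-LD contact site.
#'
#' @param foci data.frame from \code{\link{detect_foci}}.
#' @param droplets an \code{ld_droplets} object.
#' @param params a \code{\link{foci_params}}.
#' @param cluster_threshold_px boundary-gap threshold defining a contact
#'   (default 2 px).
#' @return A list with \code{foci} (input plus \code{assigned_ld_ids}
#'   semicolon string, \code{at_contact_site}), \code{per_ld} (data.frame
#'   \code{ld_id}, \code{n_patches}) over eligible LDs and
#'   \code{per_pair} (data.frame \code{ld_i}, \code{ld_j},
#'   \code{n_contact_patches}).
#' @export
assign_foci <- function(foci, droplets, params = foci_params(),
                        cluster_threshold_px = 2) {
  stopifnot(inherits(droplets, "ld_droplets"))
  tab <- droplets$table
  eligible <- which(tab$equivalent_diameter_um >= params$min_ld_diameter_um)
  rad_px <- params$assign_radius_um / droplets$pixel_size_um
  n_f <- nrow(foci)
  assigned <- character(n_f)
  contact <- logical(n_f)
  counts <- setNames(integer(length(eligible)), tab$id[eligible])
  pair_counts <- list()
  for (i in seq_len(n_f)) {
    if (length(eligible) == 0) break
    d <- vapply(eligible, function(k) {
      b <- droplets$boundary[[k]]
      if (nrow(b) == 0) b <- droplets$px[[k]]
      inside <- droplets$labels[round(foci$row[i]), round(foci$col[i])] ==
        tab$id[k]
      if (isTRUE(inside)) 0
      else min(sqrt((b[, 1] - foci$row[i])^2 + (b[, 2] - foci$col[i])^2))
    }, numeric(1))
    hit <- which(d <= rad_px)
    if (length(hit) == 0) next
    if (length(hit) > 2) {
      ord <- order(d[hit], tab$id[eligible][hit])
      hit <- hit[ord[1:2]]
    }
    ids <- sort(tab$id[eligible][hit])
    assigned[i] <- paste(ids, collapse = ";")
    counts[as.character(ids)] <- counts[as.character(ids)] + 1L
    if (length(ids) == 2) {
      ka <- match(ids[1], tab$id); kb <- match(ids[2], tab$id)
      gap <- boundary_gap(droplets$boundary[[ka]], droplets$boundary[[kb]])
      if (gap <= cluster_threshold_px) {
        contact[i] <- TRUE
        key <- paste(ids, collapse = ";")
        pair_counts[[key]] <- (pair_counts[[key]] %||% 0L) + 1L
      }
    }
  }
  foci$assigned_ld_ids <- assigned
  foci$at_contact_site <- contact
  per_pair <- if (length(pair_counts)) {
    ij <- do.call(rbind, strsplit(names(pair_counts), ";"))
    data.frame(ld_i = as.integer(ij[, 1]), ld_j = as.integer(ij[, 2]),
               n_contact_patches = unlist(pair_counts, use.names = FALSE))
  } else {
    data.frame(ld_i = integer(0), ld_j = integer(0),
               n_contact_patches = integer(0))
  }
  list(foci = foci,
       per_ld = data.frame(ld_id = as.integer(names(counts)),
                           n_patches = as.integer(counts)),
       per_pair = per_pair)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
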