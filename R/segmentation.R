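#' Segmentation parameter set
#'
#' Collects the tunable parameters of the hierarchical segmentation.
#' Defaults follow common practice for cultured adherent cells imaged at
#' high magnification; all of them are exposed because the underlying
#' published toolchains leave them user-set.
#'
#' @param nucleus_diameter_px accepted nucleus equivalent-diameter range in
#'   pixels; objects outside it are discarded (default \code{c(100, 250)}).
#' @param nucleus_smooth_sigma Gaussian presmoothing sigma (px) for the
#'   nuclear channel.
#' @param otsu_window_px adaptive-Otsu window for nuclei; defaults to 4x
#'   the maximum nucleus diameter.
#' @param declump split touching nuclei by intensity watershed?
#' @param declump_tolerance watershed depth tolerance as a fraction of the
#'   smoothed foreground intensity range; valleys shallower than this are
#'   not split.
#' @param propagation_lambda regularisation of seeded propagation in
#'   \code{[0, 1]}: 0 weights local intensity differences only, larger
#'   values weight spatial distance more.
#' @param atrous_levels_small,atrous_levels_large wavelet detail levels
#'   used for the small-LD and large-LD candidate maps.
#' @param wavelet_k detection multiplier of the per-plane robust noise
#'   scale (MAD x 1.4826).
#' @param min_ld_area_px minimum accepted LD size in pixels.
#' @param merge_gap_px maximum boundary gap (px) at which two detections
#'   are considered abutting fragments of one LD (at most one background
#'   pixel between their masks).
#' @param merge_valley_fraction fragments are merged only when the minimum
#'   intensity on the straight path between their centroids exceeds this
#'   fraction of the dimmer fragment's mean intensity (i.e. no true
#'   valley); in (0, 1).
#' @return A list of class \code{segmentation_params}.
#' @export
segmentation_params <- function(nucleus_diameter_px = c(100, 250),
                                nucleus_smooth_sigma = 6,
                                otsu_window_px = NULL,
                                declump = TRUE,
                                declump_tolerance = 0.15,
                                propagation_lambda = 0.05,
                                atrous_levels_small = c(2L, 3L),
                                atrous_levels_large = c(3L, 4L),
                                wavelet_k = 3,
                                min_ld_area_px = 3,
                                merge_gap_px = 2,
                                merge_valley_fraction = 0.75) {
  stopifnot(length(nucleus_diameter_px) == 2,
            nucleus_diameter_px[1] < nucleus_diameter_px[2],
            all(nucleus_diameter_px > 0),
            nucleus_smooth_sigma > 0, declump_tolerance > 0,
            propagation_lambda >= 0, propagation_lambda <= 1,
            all(atrous_levels_small >= 1), all(atrous_levels_large >= 1),
            wavelet_k > 0, min_ld_area_px > 0,
            merge_gap_px > 0,
            merge_valley_fraction > 0, merge_valley_fraction < 1)
  if (is.null(otsu_window_px)) otsu_window_px <- 4 * nucleus_diameter_px[2]
  structure(list(nucleus_diameter_px = nucleus_diameter_px,
                 nucleus_smooth_sigma = nucleus_smooth_sigma,
                 otsu_window_px = otsu_window_px,
                 declump = declump,
                 declump_tolerance = declump_tolerance,
                 propagation_lambda = propagation_lambda,
                 atrous_levels_small = as.integer(atrous_levels_small),
                 atrous_levels_large = as.integer(atrous_levels_large),
                 wavelet_k = wavelet_k,
                 min_ld_area_px = min_ld_area_px,
                 merge_gap_px = merge_gap_px,
                 merge_valley_fraction = merge_valley_fraction),
            class = "segmentation_params")
}

#' Segment nuclei from the nuclear-stain channel
#'
#' Adaptive Otsu thresholding of the smoothed nuclear channel, hole
#' filling, optional splitting of touching nuclei by intensity watershed,
#' and a size gate keeping only objects whose equivalent diameter lies in
#' \code{nucleus_diameter_px}.
#'
#' @param nuclei_channel 2D numeric matrix.
#' @param params a \code{\link{segmentation_params}} object.
#' @return Integer label map of accepted nuclei (labels 1..n).
#' @export
segment_nuclei <- function(nuclei_channel, params = segmentation_params()) {
  if (!is.matrix(nuclei_channel)) stop("nuclei_channel must be a 2D matrix")
  sm <- EBImage::gblur(nuclei_channel, sigma = params$nucleus_smooth_sigma)
  thr <- otsu_adaptive(sm, params$otsu_window_px)
  mask <- sm > thr
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  mask <- EBImage::fillHull(mask)
  if (isTRUE(params$declump)) {
    fg <- sm[mask]
    tol <- params$declump_tolerance * diff(range(fg))
    lab <- EBImage::watershed((sm - min(sm)) * mask, tolerance = tol)
    lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  } else {
    lab <- .label8(mask)
  }
  # size gate on equivalent diameter in pixels
  cnt <- tabulate(lab[lab > 0L])
  eqd <- 2 * sqrt(cnt / pi)
  keep <- which(eqd >= params$nucleus_diameter_px[1] &
                  eqd <= params$nucleus_diameter_px[2])
  out <- matrix(0L, nrow(lab), ncol(lab))
  if (length(keep)) {
    remap <- integer(max(lab))
    remap[keep] <- seq_along(keep)
    nz <- lab > 0L
    out[nz] <- remap[lab[nz]]
  }
  out
}

#' Segment cell bodies by seeded intensity propagation
#'
#' Foreground is the cytoplasm channel above its global Otsu threshold
#' (seed nuclei are always foreground); each foreground pixel is assigned
#' to the nucleus with minimal propagation cost, a geodesic distance that
#' blends spatial distance and local intensity difference, weighted by
#' \code{propagation_lambda}. With uniform intensity this reduces to a
#' geodesic Voronoi partition around the seeds.
#'
#' @param cytoplasm_channel 2D numeric matrix.
#' @param nuclei integer label map of seed nuclei.
#' @param params a \code{\link{segmentation_params}}.
#' @return Integer cell label map; labels match the seed nucleus labels.
#' @export
segment_cells <- function(cytoplasm_channel, nuclei,
                          params = segmentation_params()) {
  stopifnot(is.matrix(cytoplasm_channel),
            identical(dim(cytoplasm_channel), dim(nuclei)))
  if (max(nuclei) == 0L)
    return(matrix(0L, nrow(nuclei), ncol(nuclei)))
  rng <- range(cytoplasm_channel)
  normed <- if (diff(rng) > 0) (cytoplasm_channel - rng[1]) / diff(rng)
            else cytoplasm_channel * 0
  thr <- otsu_global(cytoplasm_channel)
  mask <- cytoplasm_channel > thr | nuclei > 0L
  lab <- EBImage::propagate(normed, seeds = nuclei, mask = mask,
                            lambda = params$propagation_lambda)
  matrix(as.integer(lab), nrow(lab), ncol(lab))
}

#' Detect lipid droplets with the a-trous wavelet spot detector
#'
#' Small-LD and large-LD candidate maps are built separately: a pixel is a
#' candidate at a scale set when every selected detail plane exceeds
#' \code{wavelet_k} times that plane's robust noise scale (median absolute
#' deviation x 1.4826). Every candidate region is then refined locally:
#' an intensity watershed subdivides it so that neighbouring spots of
#' unequal brightness keep their own peaks, and each subcomponent is cut
#' at its own half-maximum above the local background, which for a
#' blurred disc recovers approximately the disc's support. The two scale
#' maps are merged with overlap resolution — a large-scale detection
#' replaces all small-scale detections it overlaps — and components below
#' \code{min_ld_area_px} are discarded. Each LD is assigned to the cell
#' containing its centroid.
#'
#' @param ld_channel 2D numeric matrix (typically a maximum projection).
#' @param cells integer cell label map, or \code{NULL} to skip ownership.
#' @param params a \code{\link{segmentation_params}}.
#' @param pixel_size_um pixel size in um/px (required).
#' @return An \code{\link{droplet_records}} object (\code{ld_droplets}).
#' @export
detect_droplets <- function(ld_channel, cells = NULL,
                            params = segmentation_params(),
                            pixel_size_um) {
  if (missing(pixel_size_um) || is.null(pixel_size_um))
    stop("missing calibration: pixel_size_um is required")
  stopifnot(is.matrix(ld_channel))
  n_lev <- max(params$atrous_levels_small, params$atrous_levels_large)
  w <- atrous_decompose(ld_channel, n_lev)
  cand_at <- function(levels) {
    # multiscale correlation: every selected plane must exceed its own
    # robust noise scale (MAD x 1.4826, floored relative to the plane
    # maximum so that noise-free images yield no spurious candidates);
    # candidate components must additionally peak above a higher multiple
    # of the noise scale of the summed planes, which rejects connected
    # noise excursions that graze the per-pixel threshold
    ok <- matrix(TRUE, nrow(ld_channel), ncol(ld_channel))
    for (j in levels) {
      plane <- w$detail[[j]]
      noise <- max(mad(plane), 1e-6 * max(abs(plane)), .Machine$double.xmin)
      ok <- ok & (plane > params$wavelet_k * noise)
    }
    if (!any(ok)) return(ok)
    ssum <- Reduce(`+`, w$detail[levels])
    noise_s <- max(mad(ssum), 1e-6 * max(abs(ssum)), .Machine$double.xmin)
    lab <- .label8(ok)
    peaks <- vapply(split(ssum[ok], lab[ok]), max, numeric(1))
    keep <- as.integer(names(peaks))[peaks >
                                       (params$wavelet_k + 1.5) * noise_s]
    ok & matrix(lab %in% keep, nrow(lab), ncol(lab))
  }
  small <- cand_at(params$atrous_levels_small)
  large <- cand_at(params$atrous_levels_large)
  sm <- EBImage::gblur(ld_channel, sigma = 0.7)
  lab_s <- .refine_candidates(small, ld_channel, sm)
  lab_l <- .refine_candidates(large, ld_channel, sm)
  # overlap resolution: any small detection overlapping a large detection
  # is replaced by it; surviving small detections are kept as-is
  drop_small <- unique(lab_s[lab_s > 0L & lab_l > 0L])
  lab_s[lab_s %in% drop_small] <- 0L
  lab <- lab_l
  lab[lab_s > 0L] <- max(lab_l) + lab_s[lab_s > 0L]
  cnt <- tabulate(lab[lab > 0L])
  tiny <- which(cnt < params$min_ld_area_px)
  if (length(tiny)) lab[lab %in% tiny] <- 0L
  u <- sort(unique(lab[lab > 0L]))
  lab[lab > 0L] <- match(lab[lab > 0L], u)
  droplet_records(lab, ld_channel, pixel_size_um, cells)
}

# Refine wavelet candidate regions to per-spot supports and return a label
# map. For every candidate component the local background is the median of
# a surrounding ring; the component's support (pixels above a low fraction
# of its peak) is subdivided by an intensity watershed on the smoothed
# image so that unequal neighbouring spots each keep their own peak; each
# watershed subcomponent is then cut at its own half-maximum
# (background + 0.5 x (sub-peak - background)), which for a blurred disc
# recovers approximately the disc's own support. Subcomponents keep
# distinct labels even where their masks touch.
.refine_candidates <- function(cand, img, sm) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0L, nr, nc)
  if (!any(cand)) return(out)
  lab <- .label8(cand)
  idx <- which(lab > 0L)
  coord <- arrayInd(idx, c(nr, nc))
  grp <- split(seq_along(idx), lab[idx])
  next_id <- 0L
  for (sel in grp) {
    p <- coord[sel, , drop = FALSE]
    r0 <- max(1L, min(p[, 1]) - 5L); r1 <- min(nr, max(p[, 1]) + 5L)
    c0 <- max(1L, min(p[, 2]) - 5L); c1 <- min(nc, max(p[, 2]) + 5L)
    win <- img[r0:r1, c0:c1]
    wins <- sm[r0:r1, c0:c1]
    m <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
    m[cbind(p[, 1] - r0 + 1L, p[, 2] - c0 + 1L)] <- TRUE
    near <- EBImage::dilate(m, EBImage::makeBrush(7, "disc")) > 0
    ring <- near & !(EBImage::dilate(m, EBImage::makeBrush(3, "box")) > 0)
    bg <- if (any(ring)) median(win[ring]) else min(win)
    peak <- max(wins[m])
    if (peak <= bg) next
    supp <- near & (wins > bg + 0.3 * (peak - bg))
    if (!any(supp)) next
    ws <- EBImage::watershed(pmax(wins - bg, 0) * supp,
                             tolerance = 0.05 * (peak - bg))
    ws <- matrix(as.integer(ws), nrow(ws), ncol(ws))
    for (s in seq_len(max(ws))) {
      msub <- ws == s
      psub <- max(wins[msub])
      keep <- msub & (win > bg + 0.5 * (psub - bg))
      if (!any(keep)) next
      next_id <- next_id + 1L
      blk <- out[r0:r1, c0:c1]
      blk[keep] <- next_id
      out[r0:r1, c0:c1] <- blk
    }
  }
  out
}

#' Merge fragmented detections of large droplets
#'
#' Large LDs are sometimes reported by the detector as several abutting
#' fragments. Two detections are merged when (i) their masks are within
#' \code{merge_gap_px} of each other (at most one background pixel between
#' them) and (ii) the minimum intensity along the straight path between
#' their intensity-weighted centroids exceeds
#' \code{merge_valley_fraction} times the smaller of their mean
#' intensities — i.e. there is no true intensity valley separating them.
#' Merging is applied transitively until a fixed point and merged records
#' are recomputed from the union mask, so the droplet count never
#' increases and no droplet's area ever decreases.
#'
#' @param droplets an \code{ld_droplets} object.
#' @param ld_channel the source intensity image.
#' @param params a \code{\link{segmentation_params}}.
#' @param cells optional cell label map for re-assignment.
#' @return An \code{ld_droplets} object.
#' @export
merge_fragmented <- function(droplets, ld_channel,
                             params = segmentation_params(), cells = NULL) {
  stopifnot(inherits(droplets, "ld_droplets"))
  if (.n_droplets(droplets) <= 1) return(droplets)
  px <- droplets$px
  # the valley criterion is evaluated on background-subtracted intensity,
  # so a constant camera offset cannot hide a true valley
  img_bg <- median(ld_channel)
  repeat {
    n <- length(px)
    cen <- t(vapply(seq_len(n), function(k) {
      wgt <- ld_channel[px[[k]]]
      if (sum(wgt) <= 0) wgt <- rep(1, nrow(px[[k]]))
      c(sum(px[[k]][, 1] * wgt), sum(px[[k]][, 2] * wgt)) / sum(wgt)
    }, numeric(2)))
    meanI <- vapply(px, function(p) mean(ld_channel[p]), numeric(1))
    rmax <- vapply(seq_len(n), function(k)
      sqrt(max((px[[k]][, 1] - cen[k, 1])^2 +
                 (px[[k]][, 2] - cen[k, 2])^2)), numeric(1))
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    merged_any <- FALSE
    # vectorised bounding-circle prefilter before the exact gap
    dmat <- as.matrix(dist(cen))
    near <- which(upper.tri(dmat) &
                    dmat - outer(rmax, rmax, `+`) <= params$merge_gap_px,
                  arr.ind = TRUE)
    for (kk in seq_len(nrow(near))) {
      i <- near[kk, 1]; j <- near[kk, 2]
      dctr <- dmat[i, j]
      if (.min_cross_dist(px[[i]], px[[j]]) > params$merge_gap_px) next
      ns <- max(3L, ceiling(2 * dctr))
      path <- .bilinear_sample(ld_channel,
                               seq(cen[i, 1], cen[j, 1], length.out = ns),
                               seq(cen[i, 2], cen[j, 2], length.out = ns))
      small_union <- nrow(px[[i]]) + nrow(px[[j]]) <= 12
      if (!small_union &&
          min(path) - img_bg <=
            params$merge_valley_fraction * (min(meanI[i], meanI[j]) - img_bg))
        next
      # shape gate: fragments of one droplet reassemble into a disc-like
      # union, whereas two genuinely distinct droplets form a dumbbell —
      # require the union's maximal radius to stay close to the radius of
      # the equivalent disc
      uni <- rbind(px[[i]], px[[j]])
      ctr <- colMeans(uni)
      rmax_u <- sqrt(max((uni[, 1] - ctr[1])^2 + (uni[, 2] - ctr[2])^2))
      req <- sqrt(nrow(uni) / pi)
      if (rmax_u > 1.3 * req + 0.5) next
      ri <- find(i); rj <- find(j)
      if (ri != rj) { parent[max(ri, rj)] <- min(ri, rj); merged_any <- TRUE }
    }
    if (!merged_any) break
    root <- vapply(seq_len(n), find, integer(1))
    px <- lapply(split(seq_len(n), root),
                 function(ix) do.call(rbind, px[ix]))
    names(px) <- NULL
    if (length(px) == n) break
  }
  .droplets_from_px(px, dim(ld_channel), ld_channel,
                    droplets$pixel_size_um, cells)
}
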