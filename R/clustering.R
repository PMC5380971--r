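#' Boundary gap between two droplets
#'
#' Minimum Euclidean distance, in pixels, between any pixel centre of one
#' droplet mask and any pixel centre of the other; 0 when the masks share
#' a pixel. For disjoint masks the minimum is attained on boundary pixels,
#' so only boundaries are searched. At the default calibration of
#' 0.133 um/px a 2-pixel gap corresponds to 0.266 um.
#'
#' @param px_a,px_b n x 2 (row, col) pixel matrices of the two masks, or
#'   the \code{boundary} entries of an \code{ld_droplets} object.
#' @return The gap in pixels.
#' @export
boundary_gap <- function(px_a, px_b) {
  if (is.null(px_a) || is.null(px_b) || nrow(px_a) == 0 || nrow(px_b) == 0)
    stop("boundary_gap: empty mask")
  key <- function(p) p[, 1] * 2147483L + p[, 2]
  if (any(key(px_a) %in% key(px_b))) return(0)
  .min_cross_dist(px_a, px_b)
}

#' Identify LD clusters by boundary-gap linkage
#'
#' Two LDs are linked when the distance between their boundaries is at
#' most \code{threshold_px} pixels; clusters are the connected components
#' of this relation (transitive closure), restricted to droplets of the
#' same cell. Components of size 1 are singletons, not clusters. Droplets
#' without a cell assignment are excluded. The default threshold of 2 px
#' equals 0.266 um at 0.133 um/px.
#'
#' @param droplets an \code{ld_droplets} object.
#' @param threshold_px linkage threshold in pixels (default 2).
#' @param sd_divisor \code{"n-1"} (sample, default) or \code{"n"} for the
#'   heterogeneity s.d.
#' @return A list with \code{clusters} (data.frame: \code{cluster_id},
#'   \code{cell_id}, \code{n_lds}, \code{member_ids} as a
#'   semicolon-separated string, \code{mean_area_um2}, \code{sd_area_um2}),
#'   \code{membership} (named integer vector droplet id -> cluster id, 0
#'   for singletons/unassigned) and \code{threshold_px}.
#' @export
find_clusters <- function(droplets, threshold_px = 2, sd_divisor = "n-1") {
  stopifnot(inherits(droplets, "ld_droplets"), threshold_px >= 0)
  tab <- droplets$table
  membership <- setNames(integer(nrow(tab)), tab$id)
  empty <- data.frame(cluster_id = integer(0), cell_id = integer(0),
                      n_lds = integer(0), member_ids = character(0),
                      mean_area_um2 = numeric(0), sd_area_um2 = numeric(0))
  if (nrow(tab) == 0)
    return(list(clusters = empty, membership = membership,
                threshold_px = threshold_px))
  comp_id <- rep(0L, nrow(tab))
  next_comp <- 0L
  for (cid in sort(unique(tab$cell_id[!is.na(tab$cell_id)]))) {
    ix <- which(!is.na(tab$cell_id) & tab$cell_id == cid)
    if (length(ix) < 2) next
    edges <- .gap_edges(droplets, ix, threshold_px)
    g <- igraph::make_empty_graph(n = length(ix), directed = FALSE)
    if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
    mem <- igraph::components(g)$membership
    comp_id[ix] <- mem + next_comp
    next_comp <- next_comp + max(mem)
  }
  # keep only components of size >= 2, renumber deterministically
  sizes <- table(comp_id[comp_id > 0L])
  keep <- as.integer(names(sizes)[sizes >= 2])
  rows <- list()
  cl_id <- 0L
  for (k in sort(keep)) {
    ix <- which(comp_id == k)
    cl_id <- cl_id + 1L
    membership[ix] <- cl_id
    st <- cluster_size_stats(tab$area_um2[ix], sd_divisor = sd_divisor)
    rows[[cl_id]] <- data.frame(
      cluster_id = cl_id,
      cell_id = tab$cell_id[ix[1]],
      n_lds = length(ix),
      member_ids = paste(sort(tab$id[ix]), collapse = ";"),
      mean_area_um2 = st[["mean_area_um2"]],
      sd_area_um2 = st[["sd_area_um2"]])
  }
  clusters <- if (length(rows)) do.call(rbind, rows) else empty
  list(clusters = clusters, membership = membership,
       threshold_px = threshold_px)
}

# pairwise gap edges among droplets[ix], with a bounding-circle prefilter
.gap_edges <- function(droplets, ix, threshold_px) {
  n <- length(ix)
  tab <- droplets$table
  cen <- cbind(tab$centroid_row[ix], tab$centroid_col[ix])
  rmax <- vapply(seq_len(n), function(k) {
    b <- droplets$boundary[[ix[k]]]
    if (nrow(b) == 0) b <- droplets$px[[ix[k]]]
    sqrt(max((b[, 1] - cen[k, 1])^2 + (b[, 2] - cen[k, 2])^2))
  }, numeric(1))
  out <- matrix(integer(0), 0, 2)
  for (i in seq_len(n - 1)) {
    d <- sqrt((cen[(i + 1):n, 1] - cen[i, 1])^2 +
                (cen[(i + 1):n, 2] - cen[i, 2])^2)
    cand <- which(d - rmax[i] - rmax[(i + 1):n] <= threshold_px) + i
    for (j in cand) {
      bi <- droplets$boundary[[ix[i]]]; bj <- droplets$boundary[[ix[j]]]
      if (nrow(bi) == 0) bi <- droplets$px[[ix[i]]]
      if (nrow(bj) == 0) bj <- droplets$px[[ix[j]]]
      if (boundary_gap(bi, bj) <= threshold_px)
        out <- rbind(out, c(i, j))
    }
  }
  out
}

#' Mean and heterogeneity of clustered-LD areas
#'
#' Arithmetic mean and standard deviation of the member areas of one
#' cluster; the s.d. is the cluster size-heterogeneity measure. The
#' sample divisor (n-1) is the default.
#'
#' @param areas_um2 numeric vector of >= 2 member areas in um^2.
#' @param sd_divisor \code{"n-1"} (default) or \code{"n"}.
#' @return Named numeric vector \code{c(mean_area_um2, sd_area_um2)}.
#' @export
cluster_size_stats <- function(areas_um2, sd_divisor = "n-1") {
  if (length(areas_um2) < 2)
    stop("a cluster has >= 2 members; got ", length(areas_um2), " area(s)")
  s <- sd(areas_um2)
  if (identical(sd_divisor, "n"))
    s <- s * sqrt((length(areas_um2) - 1) / length(areas_um2))
  c(mean_area_um2 = mean(areas_um2), sd_area_um2 = s)
}

#' Cluster abundance per 100 LDs, by cluster cardinality
#'
#' For one cell: the number of clusters containing exactly k droplets
#' (k = 2..5, and 6 or more pooled) per 100 LDs in that cell.
#'
#' @param n_lds_in_cell total LD count of the cell (>= 1; with 0 LDs the
#'   rate is undefined and \code{NA} is returned for every class).
#' @param cluster_sizes integer vector of cluster cardinalities in the
#'   cell (possibly empty).
#' @return Named numeric vector with entries \code{rate_2} .. \code{rate_5}
#'   and \code{rate_6plus}.
#' @export
clusters_per_100_lds <- function(n_lds_in_cell, cluster_sizes = integer(0)) {
  nm <- c("rate_2", "rate_3", "rate_4", "rate_5", "rate_6plus")
  if (is.na(n_lds_in_cell) || n_lds_in_cell < 1)
    return(setNames(rep(NA_real_, 5), nm))
  if (any(cluster_sizes < 2)) stop("cluster sizes must be >= 2")
  counts <- c(sum(cluster_sizes == 2), sum(cluster_sizes == 3),
              sum(cluster_sizes == 4), sum(cluster_sizes == 5),
              sum(cluster_sizes >= 6))
  setNames(100 * counts / n_lds_in_cell, nm)
}

#' LD size-class histogram
#'
#' Bins droplet areas into left-closed, right-open classes
#' \code{[e_i, e_{i+1})}. The default edges (0, 0.5, 1, 1.5, 2, Inf um^2)
#' follow the convention that small LDs below 0.5 um^2 dominate the
#' population in untreated cells.
#'
#' @param droplets an \code{ld_droplets} object or a numeric vector of
#'   areas in um^2.
#' @param bin_edges_um2 strictly increasing bin edges.
#' @param per_cell also tabulate per cell (requires an \code{ld_droplets}
#'   input)?
#' @return A list with \code{counts}, \code{fractions} (named by bin) and,
#'   when \code{per_cell}, a data.frame \code{per_cell} with one row per
#'   cell and one column per bin.
#' @export
size_histogram <- function(droplets,
                           bin_edges_um2 = c(0, 0.5, 1, 1.5, 2, Inf),
                           per_cell = inherits(droplets, "ld_droplets")) {
  if (any(diff(bin_edges_um2) <= 0))
    stop("bin_edges_um2 must be strictly increasing")
  areas <- if (inherits(droplets, "ld_droplets")) droplets$table$area_um2
           else as.numeric(droplets)
  nb <- length(bin_edges_um2) - 1L
  lab <- paste0("[", head(bin_edges_um2, -1), ",", tail(bin_edges_um2, -1),
                ")")
  bin_of <- function(a) {
    b <- findInterval(a, bin_edges_um2, left.open = FALSE)
    b[b > nb | a >= bin_edges_um2[nb + 1L]] <- NA_integer_
    b[a < bin_edges_um2[1L]] <- NA_integer_
    b
  }
  b <- bin_of(areas)
  counts <- setNames(tabulate(b, nbins = nb), lab)
  fr <- if (length(areas)) counts / length(areas) else counts * NA_real_
  out <- list(counts = counts, fractions = fr)
  if (per_cell && inherits(droplets, "ld_droplets")) {
    tab <- droplets$table
    cells <- sort(unique(tab$cell_id[!is.na(tab$cell_id)]))
    pc <- matrix(0L, length(cells), nb, dimnames = list(NULL, lab))
    for (i in seq_along(cells)) {
      bi <- bin_of(tab$area_um2[!is.na(tab$cell_id) &
                                  tab$cell_id == cells[i]])
      pc[i, ] <- tabulate(bi, nbins = nb)
    }
    out$per_cell <- data.frame(cell_id = cells, pc, check.names = FALSE)
  }
  out
}
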