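#' Specification of a synthetic imaging field
#'
#' Describes a synthetic multi-channel field with cells (one nucleus
#' each), lipid droplets with a right-skewed area distribution, planted
#' LD clusters, optional marker foci, a Gaussian approximation of the
#' point-spread function and Poisson-Gaussian noise. The defaults emulate
#' oleic-acid-loaded cultured cells at high magnification: roughly one
#' hundred LDs per cell, the overwhelming majority below 0.5 um^2, and a
#' minority of the LDs engaged in clusters whose boundary gaps satisfy
#' the 2-pixel (0.266 um) clustering criterion.
#'
#' @param width_px,height_px field size in pixels.
#' @param pixel_size_um um per pixel (default 0.133; 2 px = 0.266 um).
#' @param n_cells number of cells to place.
#' @param nucleus_diameter_px_range (lo, hi) nucleus diameters in px.
#' @param cell_radius_factor cell radius as a multiple of the nucleus
#'   radius.
#' @param ld_count_per_cell list(mean=) of the per-cell Poisson LD count.
#' @param ld_area_um2_distribution list(meanlog=, sdlog=, min_um2=,
#'   max_um2=) log-normal LD area parameters with truncation; the default
#'   puts ~90\% of areas below 0.5 um^2 and truncates at the optical
#'   resolution limit.
#' @param cluster_fraction fraction of each cell's LDs placed in clusters
#'   (in \code{[0, 1]}).
#' @param cluster_size_weights sampling weights for cluster cardinalities
#'   2..5 (clusters of two dominate, as observed in loaded cells).
#' @param cluster_gap_px target planted boundary gap between clustered
#'   neighbours, in pixels; values up to 2 are rasterised to an exact
#'   2.0-px pixel-centre gap (one background pixel) so the planted
#'   partition is unambiguous under the clustering rule.
#' @param min_separation_px minimum boundary gap between LDs that are not
#'   cluster mates.
#' @param snr peak foreground signal over background noise s.d.;
#'   \code{Inf} renders noise-free.
#' @param psf_sigma_px Gaussian blur sigma in px; 0 disables blurring.
#' @param marker also render a marker z-stack with planted foci?
#' @param marker_n_z number of z-planes of the marker stack.
#' @param foci_per_ld_mean Poisson mean of planted surface foci per
#'   resolvable LD (LD radius >= 3 px).
#' @param contact_focus_prob probability that an intra-cluster contact
#'   carries a planted contact-site focus.
#' @param seed integer seed; the same spec and seed reproduce the field
#'   bit-identically.
#' @return A list of class \code{field_spec}.
#' @export
field_spec <- function(width_px = 640, height_px = 640,
                       pixel_size_um = 0.133,
                       n_cells = 2,
                       nucleus_diameter_px_range = c(100, 140),
                       cell_radius_factor = 2.0,
                       ld_count_per_cell = list(mean = 100),
                       ld_area_um2_distribution = list(meanlog = log(0.15),
                                                       sdlog = 0.8,
                                                       min_um2 = 0.07,
                                                       max_um2 = 4),
                       cluster_fraction = 0.3,
                       cluster_size_weights = c(0.55, 0.25, 0.13, 0.07),
                       cluster_gap_px = c(1, 2),
                       min_separation_px = 3,
                       snr = 10, psf_sigma_px = 0.8,
                       marker = FALSE, marker_n_z = 7,
                       foci_per_ld_mean = 3,
                       contact_focus_prob = 1,
                       seed = 1L) {
  stopifnot(width_px > 0, height_px > 0, pixel_size_um > 0, n_cells > 0,
            length(nucleus_diameter_px_range) == 2,
            all(nucleus_diameter_px_range > 0),
            nucleus_diameter_px_range[1] <= nucleus_diameter_px_range[2],
            cell_radius_factor > 1,
            ld_count_per_cell$mean > 0,
            cluster_fraction >= 0, cluster_fraction <= 1,
            length(cluster_gap_px) == 2, all(cluster_gap_px > 0),
            min_separation_px > 2,
            snr > 0, psf_sigma_px >= 0, marker_n_z >= 1,
            foci_per_ld_mean >= 0,
            contact_focus_prob >= 0, contact_focus_prob <= 1)
  structure(as.list(environment()), class = "field_spec")
}

#' Generate a synthetic field with planted ground truth
#'
#' Places cells, nuclei and LDs according to the field specification,
#' renders the
#' nuclear, cytoplasm and LD channels (plus an optional marker z-stack)
#' as blurred indicator images with Poisson-Gaussian noise at the
#' requested SNR, and returns the complete ground truth: label maps,
#' planted areas, the planted cluster partition and planted foci.
#'
#' The noise model adds a constant background of 100 photons with Poisson
#' shot noise and Gaussian read noise (s.d. 3), and scales the foreground
#' amplitude so that the peak signal over the background noise s.d.
#' equals \code{snr}. With \code{snr = Inf} the clean blurred image is
#' returned on a [0, 1] scale.
#'
#' @param spec a \code{\link{field_spec}}.
#' @return A list with \code{image} (a \code{\link{field_image}} with
#'   channels \code{nuclei}, \code{cytoplasm}, \code{ld} and optionally
#'   \code{marker}) and \code{truth} (list: \code{nucleus_masks},
#'   \code{cell_masks}, \code{ld_masks}, \code{ld_table},
#'   \code{ld_areas_um2}, \code{planted_clusters}, \code{planted_foci}).
#' @export
generate_field <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  set.seed(spec$seed)
  nr <- spec$height_px; nc <- spec$width_px
  cells <- .place_cells(spec, nr, nc)
  nucleus_masks <- matrix(0L, nr, nc)
  cell_masks <- matrix(0L, nr, nc)
  for (k in seq_len(nrow(cells))) {
    npx <- .disc_pixels(cells$row[k], cells$col[k], cells$nucleus_r[k],
                        nr, nc, q = cells$q[k], theta = cells$theta[k])
    cpx <- .disc_pixels(cells$row[k], cells$col[k], cells$cell_r[k], nr, nc)
    cell_masks[cpx] <- k
    nucleus_masks[npx] <- k
  }
  lds <- .place_lds(spec, cells, nr, nc)
  ld_masks <- matrix(0L, nr, nc)
  for (k in seq_len(nrow(lds$table))) ld_masks[lds$px[[k]]] <- k
  areas <- vapply(lds$px, nrow, integer(1)) * spec$pixel_size_um^2
  lds$table$area_um2 <- areas
  foci <- NULL
  if (isTRUE(spec$marker))
    foci <- .plant_foci(spec, lds, nr, nc)
  img <- .render_field(spec, nucleus_masks, cell_masks, ld_masks, foci,
                       nr, nc)
  truth <- list(nucleus_masks = nucleus_masks, cell_masks = cell_masks,
                ld_masks = ld_masks, ld_table = lds$table,
                ld_areas_um2 = areas,
                planted_clusters = lds$clusters,
                planted_foci = foci)
  list(image = img, truth = truth)
}

#' Write a synthetic field and its ground truth to disk
#'
#' Writes the rendered channels as one multi-page TIFF, the ground-truth
#' label maps as separate TIFFs, and the remaining ground truth (areas,
#' planted clusters and foci, the generating spec) as a JSON sidecar.
#'
#' @param field result of \code{\link{generate_field}}.
#' @param dir output directory (created if needed).
#' @return Named vector of the written paths, invisibly.
#' @export
write_synthetic_field <- function(field, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(image = file.path(dir, "field.tif"),
             nuclei = file.path(dir, "nucleus_labels.tif"),
             cells = file.path(dir, "cell_labels.tif"),
             lds = file.path(dir, "ld_labels.tif"),
             truth = file.path(dir, "ground_truth.json"))
  img2d <- field$image
  img2d$channels <- field$image$channels[c("nuclei", "cytoplasm", "ld")]
  write_field(img2d, paths["image"])
  write_label_map(field$truth$nucleus_masks, paths["nuclei"])
  write_label_map(field$truth$cell_masks, paths["cells"])
  write_label_map(field$truth$ld_masks, paths["lds"])
  tr <- field$truth
  jsonlite::write_json(list(ld_table = tr$ld_table,
                            ld_areas_um2 = tr$ld_areas_um2,
                            planted_clusters = tr$planted_clusters,
                            planted_foci = tr$planted_foci),
                       paths["truth"], auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(paths)
}

.placement_fail <- function(what, budget) {
  stop("geometric infeasibility: could not place ", what, " within ",
       budget, " attempts; reduce object count or size, or enlarge ",
       "the field")
}

.place_cells <- function(spec, nr, nc) {
  n <- spec$n_cells
  budget <- 5000L
  rows <- cols <- nuc_r <- cell_r <- q <- theta <- numeric(n)
  for (k in seq_len(n)) {
    d <- runif(1, spec$nucleus_diameter_px_range[1],
               spec$nucleus_diameter_px_range[2])
    nuc_r[k] <- d / 2
    cell_r[k] <- min(d / 2 * spec$cell_radius_factor,
                     (min(nr, nc) - 8) / 2)
    q[k] <- runif(1, 0.9, 1)
    theta[k] <- runif(1, 0, pi)
    placed <- FALSE
    for (a in seq_len(budget)) {
      r0 <- runif(1, cell_r[k] + 3, nr - cell_r[k] - 3)
      c0 <- runif(1, cell_r[k] + 3, nc - cell_r[k] - 3)
      if (k == 1 || all(sqrt((rows[seq_len(k - 1)] - r0)^2 +
                               (cols[seq_len(k - 1)] - c0)^2) >=
                          cell_r[seq_len(k - 1)] + cell_r[k] + 6)) {
        rows[k] <- r0; cols[k] <- c0; placed <- TRUE; break
      }
    }
    if (!placed)
      .placement_fail(sprintf("cell %d of %d (radius %.0f px)", k, n,
                              cell_r[k]), budget)
  }
  data.frame(row = rows, col = cols, nucleus_r = nuc_r, cell_r = cell_r,
             q = q, theta = theta)
}

# sample LD areas, partition a fraction into clusters and place them so
# the rasterised geometry respects the planted cluster partition
.place_lds <- function(spec, cells, nr, nc) {
  dist <- spec$ld_area_um2_distribution
  px_area <- spec$pixel_size_um^2
  budget <- 5000L
  all_px <- list(); tab <- list(); clusters <- list()
  gid <- 0L; cl_id <- 0L
  for (ci in seq_len(nrow(cells))) {
    n_ld <- max(1L, rpois(1, spec$ld_count_per_cell$mean))
    a <- pmin(pmax(rlnorm(n_ld, dist$meanlog, dist$sdlog), dist$min_um2),
              dist$max_um2)
    r_px <- sqrt(a / px_area / pi)
    groups <- .plan_clusters(n_ld, spec$cluster_fraction,
                             spec$cluster_size_weights)
    ord <- order(groups, method = "radix")   # cluster mates consecutive
    r_px <- r_px[ord]; groups <- groups[ord]
    inner <- cells$nucleus_r[ci] + 2
    outer <- cells$cell_r[ci] - 2
    # a rejection-sampled layout can occasionally jam locally; in that
    # case the whole cell is laid out afresh before declaring the
    # geometry infeasible
    cell_done <- FALSE
    last_fail <- NULL
    for (layout_try in 1:5) {
    placed_ctr <- matrix(numeric(0), 0, 2)
    placed_r <- numeric(0)
    placed_px <- list()
    cell_done <- TRUE
    for (k in seq_len(n_ld)) {
      rk <- max(r_px[k], 0.9)
      anchor <- if (groups[k] > 0 && k > 1 && groups[k - 1] == groups[k])
        which(groups[seq_len(k - 1)] == groups[k]) else integer(0)
      ok <- FALSE
      for (att in seq_len(budget)) {
        if (length(anchor)) {
          # scan a fine distance grid along a random direction from the
          # anchor: the rasterised gap is a step function of the centre
          # distance, so the admissible plateau is found deterministically
          j <- anchor[sample.int(length(anchor), 1)]
          ang <- runif(1, 0, 2 * pi)
          base <- placed_r[j] + rk
          cand_d <- seq(base + min(spec$cluster_gap_px) - 0.4,
                        base + max(spec$cluster_gap_px) + 0.6, by = 0.1)
          for (dctr in cand_d) {
            r0 <- placed_ctr[j, 1] + dctr * cos(ang)
            c0 <- placed_ctr[j, 2] + dctr * sin(ang)
            drc <- sqrt((r0 - cells$row[ci])^2 + (c0 - cells$col[ci])^2)
            if (drc + rk > outer || drc - rk < inner) next
            cand <- .disc_pixels(r0, c0, rk, nr, nc)
            if (is.null(cand) || nrow(cand) == 0) next
            if (.ld_position_ok(cand, r0, c0, rk, k, groups, placed_ctr,
                                placed_r, placed_px, spec)) {
              ok <- TRUE
              break
            }
          }
        } else {
          rad <- sqrt(runif(1, (inner + rk)^2, max((outer - rk)^2,
                                                   (inner + rk)^2 + 1)))
          ang <- runif(1, 0, 2 * pi)
          r0 <- cells$row[ci] + rad * cos(ang)
          c0 <- cells$col[ci] + rad * sin(ang)
          drc <- sqrt((r0 - cells$row[ci])^2 + (c0 - cells$col[ci])^2)
          if (drc + rk > outer || drc - rk < inner) next
          cand <- .disc_pixels(r0, c0, rk, nr, nc)
          if (is.null(cand) || nrow(cand) == 0) next
          if (.ld_position_ok(cand, r0, c0, rk, k, groups, placed_ctr,
                              placed_r, placed_px, spec)) ok <- TRUE
        }
        if (ok) {
          placed_ctr <- rbind(placed_ctr, c(r0, c0))
          placed_r <- c(placed_r, rk)
          placed_px[[k]] <- cand
          break
        }
      }
      if (!ok) {
        if (length(anchor)) {
          # demote an unplaceable cluster member to a singleton
          groups[k] <- 0L
          for (att in seq_len(budget)) {
            rad <- sqrt(runif(1, (inner + rk)^2,
                              max((outer - rk)^2, (inner + rk)^2 + 1)))
            ang <- runif(1, 0, 2 * pi)
            r0 <- cells$row[ci] + rad * cos(ang)
            c0 <- cells$col[ci] + rad * sin(ang)
            cand <- .disc_pixels(r0, c0, rk, nr, nc)
            if (is.null(cand) || nrow(cand) == 0) next
            if (.ld_position_ok(cand, r0, c0, rk, k, groups, placed_ctr,
                                placed_r, placed_px, spec)) {
              placed_ctr <- rbind(placed_ctr, c(r0, c0))
              placed_r <- c(placed_r, rk)
              placed_px[[k]] <- cand
              ok <- TRUE
              break
            }
          }
        }
        if (!ok) {
          last_fail <- sprintf("LD %d of %d in cell %d (radius %.1f px)",
                               k, n_ld, ci, rk)
          cell_done <- FALSE
          break
        }
      }
    }
    if (cell_done) break
    }
    if (!cell_done) .placement_fail(last_fail, budget)
    ids <- gid + seq_len(n_ld)
    gid <- gid + n_ld
    for (g in setdiff(unique(groups), 0L)) {
      mem <- ids[groups == g]
      if (length(mem) >= 2) {
        cl_id <- cl_id + 1L
        clusters[[cl_id]] <- mem
      }
    }
    all_px <- c(all_px, placed_px)
    tab[[ci]] <- data.frame(id = ids, cell_id = ci,
                            centroid_row = placed_ctr[, 1],
                            centroid_col = placed_ctr[, 2],
                            radius_px = placed_r,
                            cluster = ifelse(groups > 0, groups + ci * 1e4,
                                             0))
  }
  list(px = all_px, table = do.call(rbind, tab), clusters = clusters)
}

# acceptance test for a candidate LD mask against the planted geometry:
# cluster mates must sit at a pixel-centre gap that satisfies the planted
# gap (exactly 2.0 px for targets <= 2), everyone else must stay at least
# min_separation_px away
.ld_position_ok <- function(cand, r0, c0, rk, k, groups, placed_ctr,
                            placed_r, placed_px, spec) {
  if (nrow(placed_ctr) == 0) return(TRUE)
  n_prev <- nrow(placed_ctr)
  d <- sqrt((placed_ctr[, 1] - r0)^2 + (placed_ctr[, 2] - c0)^2)
  mates <- groups[seq_len(n_prev)] == groups[k] & groups[k] > 0L
  # quick reject on continuous gaps
  if (any(!mates & d - placed_r - rk < spec$min_separation_px + 1))
    return(FALSE)
  adj <- which(mates & d - placed_r - rk < 4)
  if (groups[k] > 0L && any(mates) && length(adj) == 0) return(FALSE)
  for (j in adj) {
    g <- .min_cross_dist(cand, placed_px[[j]])
    tgt <- spec$cluster_gap_px[2]
    if (tgt <= 2) {
      if (abs(g - 2) > 1e-9) return(FALSE)
    } else {
      if (g < 2 || abs(g - mean(spec$cluster_gap_px)) > 1) return(FALSE)
    }
  }
  # non-mates that are near by centroid: verify pixel gap
  near <- which(!mates & d - placed_r - rk < spec$min_separation_px + 3)
  for (j in near)
    if (.min_cross_dist(cand, placed_px[[j]]) < spec$min_separation_px)
      return(FALSE)
  TRUE
}

# partition n LDs into cluster groups (0 = singleton); group labels are
# small positive integers local to the cell
.plan_clusters <- function(n, fraction, weights) {
  groups <- integer(n)
  n_clustered <- round(fraction * n)
  if (n_clustered < 2) return(groups)
  remaining <- n_clustered
  g <- 0L
  pos <- 1L
  while (remaining >= 2) {
    sz <- sample(2:5, 1, prob = weights)
    sz <- min(sz, remaining)
    if (sz < 2) break
    g <- g + 1L
    groups[pos:(pos + sz - 1L)] <- g
    pos <- pos + sz
    remaining <- remaining - sz
  }
  groups
}

# plant marker foci: contact foci at planted intra-cluster contacts
# first, then surface foci on resolvable LDs. Foci are kept mutually
# separated (laterally or axially) so that each remains an individual
# diffraction-limited patch after rendering.
.plant_foci <- function(spec, lds, nr, nc) {
  tab <- lds$table
  n_z <- spec$marker_n_z
  rows <- list()
  fid <- 0L
  far_enough <- function(r0, c0, z0) {
    if (fid == 0) return(TRUE)
    for (e in rows) {
      if (sqrt((e$row - r0)^2 + (e$col - c0)^2) < 4 &&
          abs(e$z - z0) < 3) return(FALSE)
    }
    TRUE
  }
  for (cl in lds$clusters) {
    mem <- match(cl, tab$id)
    for (i in seq_along(mem)[-1]) {
      # contact with the nearest earlier member (the placement anchor
      # chain guarantees adjacency within the cluster)
      d <- sqrt((tab$centroid_row[mem[seq_len(i - 1)]] -
                   tab$centroid_row[mem[i]])^2 +
                  (tab$centroid_col[mem[seq_len(i - 1)]] -
                     tab$centroid_col[mem[i]])^2)
      j <- mem[which.min(d)]
      # contact patches are only countable between droplets above the
      # 1 um eligibility diameter; plant them only there (radius 4 px at
      # the default calibration is safely above it)
      if (tab$radius_px[mem[i]] < 4 || tab$radius_px[j] < 4) next
      if (runif(1) > spec$contact_focus_prob) next
      # place the focus at the middle of the boundary gap (equidistant
      # from both droplet surfaces), so it lies within assignment reach
      # of both partners
      dctr <- min(d)
      u <- c(tab$centroid_row[mem[i]] - tab$centroid_row[j],
             tab$centroid_col[mem[i]] - tab$centroid_col[j]) / dctr
      reach <- tab$radius_px[j] +
        (dctr - tab$radius_px[j] - tab$radius_px[mem[i]]) / 2
      fid <- fid + 1L
      rows[[fid]] <- data.frame(
        id = fid,
        z = sample.int(n_z, 1),
        row = tab$centroid_row[j] + u[1] * reach,
        col = tab$centroid_col[j] + u[2] * reach,
        intensity = runif(1, 0.8, 1.2),
        ld_ids = paste(sort(c(tab$id[j], tab$id[mem[i]])), collapse = ";"),
        contact = TRUE)
    }
  }
  # a surface focus must not sit in another droplet's assignment reach,
  # otherwise it would read as a contact-site patch
  clear_of_others <- function(r0, c0, k) {
    for (j in seq_len(nrow(tab))) {
      if (j == k) next
      dctr <- sqrt((tab$centroid_row[j] - r0)^2 +
                     (tab$centroid_col[j] - c0)^2)
      if (dctr - tab$radius_px[j] < 3.5) return(FALSE)
    }
    TRUE
  }
  for (k in seq_len(nrow(tab))) {
    if (tab$radius_px[k] < 3) next
    n_f <- rpois(1, spec$foci_per_ld_mean)
    if (n_f == 0) next
    for (i in seq_len(n_f)) {
      for (att in 1:40) {
        ang <- runif(1, 0, 2 * pi)
        z0 <- sample.int(n_z, 1)
        r0 <- tab$centroid_row[k] + tab$radius_px[k] * cos(ang)
        c0 <- tab$centroid_col[k] + tab$radius_px[k] * sin(ang)
        if (!far_enough(r0, c0, z0)) next
        if (!clear_of_others(r0, c0, k)) next
        fid <- fid + 1L
        rows[[fid]] <- data.frame(
          id = fid, z = z0, row = r0, col = c0,
          intensity = runif(1, 0.8, 1.2),
          ld_ids = as.character(tab$id[k]),
          contact = FALSE)
        break
      }
    }
  }
  if (fid == 0) return(NULL)
  do.call(rbind, rows)
}

# render channels: blurred indicators, amplitude-scaled, Poisson-Gaussian
# noise calibrated to the requested SNR
.render_field <- function(spec, nucleus_masks, cell_masks, ld_masks, foci,
                          nr, nc) {
  blur <- function(m) {
    if (spec$psf_sigma_px > 0) EBImage::gblur(m, sigma = spec$psf_sigma_px)
    else m
  }
  clean_n <- blur((nucleus_masks > 0) * 1)
  clean_c <- blur((cell_masks > 0) * 1)
  clean_l <- blur((ld_masks > 0) * 1)
  chans <- list(nuclei = .apply_noise(clean_n, spec$snr),
                cytoplasm = .apply_noise(clean_c, spec$snr),
                ld = .apply_noise(clean_l, spec$snr))
  if (!is.null(foci) || isTRUE(spec$marker)) {
    stack <- array(0, dim = c(nr, nc, spec$marker_n_z))
    if (!is.null(foci)) {
      sig_l <- 1.5; sig_z <- 1
      for (i in seq_len(nrow(foci))) {
        rr <- max(1, floor(foci$row[i] - 5)):min(nr, ceiling(foci$row[i] + 5))
        cc <- max(1, floor(foci$col[i] - 5)):min(nc, ceiling(foci$col[i] + 5))
        for (z in seq_len(spec$marker_n_z)) {
          az <- exp(-(z - foci$z[i])^2 / (2 * sig_z^2))
          if (az < 1e-3) next
          g <- outer(exp(-(rr - foci$row[i])^2 / (2 * sig_l^2)),
                     exp(-(cc - foci$col[i])^2 / (2 * sig_l^2)))
          stack[rr, cc, z] <- stack[rr, cc, z] + foci$intensity[i] * az * g
        }
      }
    }
    for (z in seq_len(spec$marker_n_z))
      stack[, , z] <- .apply_noise(stack[, , z], spec$snr)
    chans$marker <- stack
  }
  field_image(chans, pixel_size_um = spec$pixel_size_um)
}

# Poisson-Gaussian noise: background of 100 photons (shot noise) plus
# Gaussian read noise of s.d. 3; foreground gain chosen so that
# peak / sd(background) = snr. snr = Inf returns the clean image.
.apply_noise <- function(clean, snr) {
  if (!is.finite(snr)) return(clean)
  bg <- 100; read_sd <- 3
  sigma_bg <- sqrt(bg + read_sd^2)
  gain <- snr * sigma_bg
  lam <- pmax(clean, 0) * gain + bg
  out <- rpois(length(lam), lam) + rnorm(length(lam), 0, read_sd)
  matrix(out, nrow(clean), ncol(clean))
}
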