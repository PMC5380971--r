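#' Pipeline configuration
#'
#' Gathers all stage parameters, calibration and I/O paths of the two
#' pipelines (still-image morphometry, time-lapse dynamics) into one
#' object that round-trips losslessly through YAML. Every run writes the
#' fully resolved configuration beside its outputs so any result can be
#' reproduced from its sidecar.
#'
#' @param input input TIFF path(s), or \code{NULL} when images are passed
#'   in memory.
#' @param output_dir directory for tables, label maps and the resolved
#'   config.
#' @param pixel_size_um,frame_interval_s calibration.
#' @param segmentation a \code{\link{segmentation_params}}.
#' @param cluster_threshold_px boundary-gap clustering threshold.
#' @param size_bins_um2 area histogram bin edges.
#' @param foci a \code{\link{foci_params}}.
#' @param max_displacement_um,max_missing,persistence_frames,window_s
#'   dynamics parameters (see the respective functions).
#' @param association_threshold_px boundary-gap threshold for per-frame
#'   pair states in time-lapse series. The default (4 px) is two pixels
#'   looser than the fixed-cell clustering criterion to absorb the
#'   single-pixel boundary jitter of per-frame masks under noise;
#'   dissociating pairs separate far beyond it.
#' @param roi_radius_um,pre_window_frames marker-scoring parameters.
#' @param detection_method \code{"atrous"} (wavelet spot detector) or
#'   \code{"threshold"} (robust background threshold with local
#'   half-maximum refinement), the latter suited to high-contrast
#'   label-free time-lapse frames.
#' @param seed integer seed recorded with the run.
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(input = NULL, output_dir = tempfile("lipodrop"),
                            pixel_size_um = 0.133, frame_interval_s = 2,
                            segmentation = segmentation_params(),
                            cluster_threshold_px = 2,
                            size_bins_um2 = c(0, 0.5, 1, 1.5, 2, Inf),
                            foci = foci_params(),
                            max_displacement_um = 1.2, max_missing = 4,
                            persistence_frames = 3, window_s = 300,
                            association_threshold_px = 4,
                            roi_radius_um = 0.3, pre_window_frames = 5,
                            detection_method = c("atrous", "threshold"),
                            seed = 1L) {
  detection_method <- match.arg(detection_method)
  structure(list(input = input, output_dir = output_dir,
                 pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s,
                 segmentation = segmentation,
                 cluster_threshold_px = cluster_threshold_px,
                 size_bins_um2 = size_bins_um2,
                 foci = foci,
                 max_displacement_um = max_displacement_um,
                 max_missing = max_missing,
                 persistence_frames = persistence_frames,
                 window_s = window_s,
                 association_threshold_px = association_threshold_px,
                 roi_radius_um = roi_radius_um,
                 pre_window_frames = pre_window_frames,
                 detection_method = detection_method,
                 seed = seed),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param path YAML file path.
#' @return \code{write_config}: \code{path}, invisibly;
#'   \code{read_config}: a \code{pipeline_config}.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$segmentation <- unclass(x$segmentation)
  x$foci <- unclass(x$foci)
  x$size_bins_um2 <- ifelse(is.infinite(x$size_bins_um2), ".inf",
                            as.character(x$size_bins_um2))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$size_bins_um2 <- as.numeric(ifelse(x$size_bins_um2 == ".inf", Inf,
                                       x$size_bins_um2))
  cfg <- pipeline_config()
  for (nm in names(x)) cfg[[nm]] <- x[[nm]]
  cfg$segmentation <- do.call(segmentation_params,
                              x$segmentation[setdiff(
                                names(x$segmentation), "otsu_window_px")])
  cfg$segmentation$otsu_window_px <- x$segmentation$otsu_window_px
  cfg$foci <- do.call(foci_params, x$foci)
  cfg
}

#' Run the still-image morphometry pipeline
#'
#' Executes the full hierarchy on one field: optional maximum projection,
#' nucleus segmentation, seeded cell propagation, wavelet LD detection,
#' fragment-merge correction, boundary-gap clustering and the per-cell
#' statistics; writes droplet, cluster and per-cell summary CSVs, label
#' maps (TIFF) and the resolved config into \code{config$output_dir}.
#' Stage-by-stage object counts are logged via \code{message()}.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param image a \code{\link{field_image}} with channels \code{nuclei},
#'   \code{cytoplasm} and \code{ld}; when \code{NULL} it is read from
#'   \code{config$input} (channel order nuclei, cytoplasm, ld).
#' @return Invisibly, a list with \code{droplets}, \code{clusters},
#'   \code{per_cell}, \code{nuclei}, \code{cells} and the output paths.
#' @export
run_morphometry <- function(config, image = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(image)) {
    if (is.null(config$input)) stop("no input image or path configured")
    image <- read_field(config$input,
                        c("nuclei", "cytoplasm", "ld"),
                        pixel_size_um = config$pixel_size_um)
  }
  chans <- lapply(image$channels[c("nuclei", "cytoplasm", "ld")],
                  max_project)
  message("morphometry: segmenting nuclei")
  nuclei <- segment_nuclei(chans$nuclei, config$segmentation)
  message("morphometry: ", max(nuclei), " nuclei")
  cells <- segment_cells(chans$cytoplasm, nuclei, config$segmentation)
  message("morphometry: ", length(setdiff(unique(as.integer(cells)), 0L)),
          " cells")
  droplets <- detect_droplets(chans$ld, cells, config$segmentation,
                              image$pixel_size_um)
  droplets <- merge_fragmented(droplets, chans$ld, config$segmentation,
                               cells)
  message("morphometry: ", nrow(droplets$table), " droplets")
  cl <- find_clusters(droplets, config$cluster_threshold_px)
  message("morphometry: ", nrow(cl$clusters), " clusters")
  per_cell <- summarize_cells(droplets, cl, config$size_bins_um2)
  paths <- c(droplets = file.path(config$output_dir, "droplets.csv"),
             clusters = file.path(config$output_dir, "clusters.csv"),
             per_cell = file.path(config$output_dir, "per_cell.csv"),
             nuclei = file.path(config$output_dir, "nuclei_labels.tif"),
             cells = file.path(config$output_dir, "cell_labels.tif"),
             lds = file.path(config$output_dir, "ld_labels.tif"),
             config = file.path(config$output_dir, "config.yaml"))
  dtab <- droplets$table
  dtab$cluster_id <- unname(cl$membership[as.character(dtab$id)])
  write_measurements(dtab, paths["droplets"])
  write_measurements(cl$clusters, paths["clusters"])
  write_measurements(per_cell, paths["per_cell"])
  write_label_map(nuclei, paths["nuclei"])
  write_label_map(cells, paths["cells"])
  write_label_map(droplets$labels, paths["lds"])
  write_config(config, paths["config"])
  invisible(list(droplets = droplets, clusters = cl, per_cell = per_cell,
                 nuclei = nuclei, cells = cells, paths = paths))
}

#' Per-cell summary statistics
#'
#' One row per cell: LD count, mean area, size-class counts, cluster
#' rates per 100 LDs by cardinality, and mean/s.d. of clustered-LD areas.
#'
#' @param droplets an \code{ld_droplets}.
#' @param clusters result of \code{\link{find_clusters}}.
#' @param size_bins_um2 histogram bin edges.
#' @return A data.frame.
#' @export
summarize_cells <- function(droplets, clusters,
                            size_bins_um2 = c(0, 0.5, 1, 1.5, 2, Inf)) {
  tab <- droplets$table
  cells <- sort(unique(tab$cell_id[!is.na(tab$cell_id)]))
  hist <- size_histogram(droplets, size_bins_um2, per_cell = TRUE)
  if (length(cells) == 0) {
    nb <- length(size_bins_um2) - 1L
    empty <- data.frame(cell_id = integer(0), n_lds = integer(0),
                        mean_area_um2 = numeric(0), n_clusters = integer(0),
                        clustered_mean_area_um2 = numeric(0),
                        clustered_sd_area_um2 = numeric(0),
                        rate_2 = numeric(0), rate_3 = numeric(0),
                        rate_4 = numeric(0), rate_5 = numeric(0),
                        rate_6plus = numeric(0))
    for (nm in paste0("bin_", seq_len(nb))) empty[[nm]] <- integer(0)
    return(empty)
  }
  rows <- lapply(cells, function(cid) {
    sel <- !is.na(tab$cell_id) & tab$cell_id == cid
    cl_sel <- clusters$clusters[clusters$clusters$cell_id == cid, ,
                                drop = FALSE]
    member_ids <- unlist(strsplit(cl_sel$member_ids, ";"))
    cl_areas <- tab$area_um2[match(as.integer(member_ids), tab$id)]
    rates <- clusters_per_100_lds(sum(sel), cl_sel$n_lds)
    cbind(data.frame(cell_id = cid, n_lds = sum(sel),
                     mean_area_um2 = mean(tab$area_um2[sel]),
                     n_clusters = nrow(cl_sel),
                     clustered_mean_area_um2 =
                       if (length(cl_areas)) mean(cl_areas) else NA_real_,
                     clustered_sd_area_um2 =
                       if (length(cl_areas) >= 2) sd(cl_areas) else NA_real_),
          as.data.frame(as.list(rates)),
          hist$per_cell[hist$per_cell$cell_id == cid, -1, drop = FALSE])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# per-frame droplet detection for time-lapse series. The "threshold"
# method cuts at half-maximum between the robust background level and the
# bright-tail intensity — appropriate for high-contrast label-free (CARS)
# frames where droplets are the only bright objects
.detect_frame <- function(frame, config) {
  det <- if (config$detection_method == "atrous") {
    detect_droplets(frame, NULL, config$segmentation,
                    config$pixel_size_um)
  } else {
    bg <- median(frame)
    madf <- mad(frame)
    pk <- quantile(frame, 0.999, names = FALSE)
    if (pk - bg < 8 * madf)
      return(.empty_droplets(matrix(0L, nrow(frame), ncol(frame)),
                             config$pixel_size_um))
    sm <- EBImage::gblur(frame, 0.7)
    supp <- frame > bg + 5 * madf
    lab0 <- .label8(supp)
    # single-peak components are cut at their own half-maximum in one
    # vectorised pass; components holding several intensity maxima
    # (associated pairs) go through the windowed watershed refinement
    idx <- which(lab0 > 0L)
    labv <- lab0[idx]
    peaks <- vapply(split(sm[idx], labv), max, numeric(1))
    mx <- .local_maxima(sm, bg + 5 * madf)
    mxl <- lab0[mx]
    multi <- as.integer(names(which(table(mxl[mxl > 0L]) >= 2L)))
    thr_px <- bg + 0.5 * (peaks[as.character(labv)] - bg)
    keep <- frame[idx] > thr_px & !(labv %in% multi)
    lab <- matrix(0L, nrow(frame), ncol(frame))
    lab[idx[keep]] <- labv[keep]
    if (length(multi)) {
      cand_m <- matrix(FALSE, nrow(frame), ncol(frame))
      cand_m[idx[labv %in% multi]] <- TRUE
      lab_m <- .refine_candidates(cand_m, frame, sm)
      lab[lab_m > 0L] <- max(lab0) + lab_m[lab_m > 0L]
    }
    u <- sort(unique(lab[lab > 0L]))
    lab[lab > 0L] <- match(lab[lab > 0L], u)
    cnt <- tabulate(lab[lab > 0L])
    tiny <- which(cnt < max(5, config$segmentation$min_ld_area_px))
    if (length(tiny)) {
      lab[lab %in% tiny] <- 0L
      u <- sort(unique(lab[lab > 0L]))
      lab[lab > 0L] <- match(lab[lab > 0L], u)
    }
    droplet_records(lab, frame, config$pixel_size_um)
  }
  merge_fragmented(det, frame, config$segmentation)
}

#' Run the time-lapse dynamics pipeline
#'
#' Detects droplets per frame, tracks them, derives pair association
#' state series, classifies associated pairs as static or dynamic over
#' the observation window, detects persistent dissociation events and —
#' when a marker channel is present — scores marker co-occurrence and
#' onset timing. Writes pair-classification and event CSVs plus the
#' resolved config.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param ld_frames list of LD-channel matrices (one per frame).
#' @param marker_frames optional list of marker-channel matrices.
#' @param score_markers score marker co-occurrence? Requires
#'   \code{marker_frames}.
#' @return Invisibly, a list with \code{tracks}, \code{series},
#'   \code{pairs} (classification data.frame), \code{events},
#'   \code{summary} and output paths.
#' @export
run_dynamics <- function(config, ld_frames, marker_frames = NULL,
                         score_markers = !is.null(marker_frames)) {
  stopifnot(inherits(config, "pipeline_config"), length(ld_frames) >= 2)
  if (score_markers && is.null(marker_frames))
    stop("marker scoring requested but no marker channel provided")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  message("dynamics: detecting droplets in ", length(ld_frames), " frames")
  dets <- lapply(ld_frames, .detect_frame, config = config)
  tracks <- track_droplets(dets, config$max_displacement_um,
                           config$max_missing, config$pixel_size_um)
  message("dynamics: ", length(tracks), " tracks")
  series <- pair_state_series(tracks, dets, config$association_threshold_px,
                              denoise = TRUE)
  message("dynamics: ", length(series), " associated pairs")
  cls <- lapply(series, function(s) {
    # only pairs associated at the start of the observation window are
    # classifiable; later transient proximities are neither static nor
    # dynamic clusters
    if (s$frames[1] > 3L || s$state[1] != 1L) return(NULL)
    classify_pair(s, config$window_s, config$frame_interval_s)
  })
  keep <- !vapply(cls, is.null, logical(1))
  pairs <- if (any(keep)) data.frame(
    pair_i = vapply(series[keep], function(s) s$pair[1], 0),
    pair_j = vapply(series[keep], function(s) s$pair[2], 0),
    class = vapply(cls[keep], function(x) x$class, ""),
    truncated = vapply(cls[keep], function(x) x$truncated, logical(1)),
    observed_to = vapply(series[keep], function(s) max(s$frames), 0L))
  else data.frame(pair_i = integer(0), pair_j = integer(0),
                  class = character(0), truncated = logical(0),
                  observed_to = integer(0))
  events <- detect_dissociations(series, config$persistence_frames)
  message("dynamics: ", nrow(events), " dissociation events")
  # the static fraction is estimated over pairs observed essentially
  # through the whole window (up to a persistence allowance of trailing
  # missed frames); pairs whose series ends early (lost or fused) are
  # censored observations and enter neither class
  window_end <- floor(config$window_s / config$frame_interval_s) + 1L
  window_end <- min(window_end, length(ld_frames))
  full <- pairs$observed_to >= window_end - config$persistence_frames
  summary <- c(n_pairs = nrow(pairs),
               n_pairs_full_window = sum(full),
               static_fraction = if (any(full))
                 mean(pairs$class[full] == "static") else NA_real_,
               n_events = nrow(events))
  if (score_markers) {
    sc <- score_marker(events, marker_frames, config$roi_radius_um,
                       config$pre_window_frames, config$pixel_size_um)
    events <- sc$events
    summary <- c(summary, sc$summary)
  }
  paths <- c(pairs = file.path(config$output_dir, "pair_classes.csv"),
             events = file.path(config$output_dir, "events.csv"),
             config = file.path(config$output_dir, "config.yaml"))
  ev_out <- events
  if (nrow(ev_out))
    ev_out$t_event_s <- (ev_out$t_event - 1) * config$frame_interval_s
  write_measurements(pairs, paths["pairs"])
  write_measurements(ev_out, paths["events"])
  write_config(config, paths["config"])
  invisible(list(tracks = tracks, series = series, pairs = pairs,
                 events = events, summary = summary, paths = paths))
}

#' Compare a per-cell statistic between two treatment groups
#'
#' Convenience two-tailed Welch t-test with group means and s.e.m.,
#' mirroring the way per-cell morphometry is usually reported (mean over
#' cells, error bars s.e.m., plain two-tailed t-test).
#'
#' @param values numeric vector of per-cell statistics.
#' @param group factor/character vector with exactly two levels.
#' @return A list with \code{means}, \code{sem} and \code{p_value}.
#' @export
compare_groups <- function(values, group) {
  g <- factor(group)
  if (nlevels(g) != 2) stop("exactly two groups required")
  sp <- split(values, g)
  list(means = vapply(sp, mean, 0, na.rm = TRUE),
       sem = vapply(sp, function(v)
         sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))), 0),
       p_value = t.test(sp[[1]], sp[[2]], var.equal = FALSE)$p.value)
}
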