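#' Track droplets across time-lapse frames
#'
#' Links per-frame detections into tracks by minimum-cost bipartite
#' matching of centroid displacements (solved exactly per frame pair),
#' gated at \code{max_displacement_um} per elapsed frame. Unmatched
#' detections start new tracks; a track not observed for more than
#' \code{max_missing} consecutive frames is terminated. A terminated
#' track whose last position falls inside a surviving detection whose
#' area is consistent with the sum of the two predecessors is annotated
#' as a fusion rather than a lost identity.
#'
#' @param frames list of \code{ld_droplets}, one per frame.
#' @param max_displacement_um gate on per-frame displacement (um).
#' @param max_missing maximum tolerated consecutive missed frames.
#' @param pixel_size_um calibration; defaults to the first frame's.
#' @return A list of tracks, each a list with \code{id}, \code{frames}
#'   (observed frame indices), \code{det} (detection row index per
#'   observed frame), \code{row}, \code{col} (centroids, px),
#'   \code{area_um2}, and optionally \code{fused_into}.
#' @export
track_droplets <- function(frames, max_displacement_um = 1.2,
                           max_missing = 4,
                           pixel_size_um = frames[[1]]$pixel_size_um) {
  stopifnot(length(frames) >= 2)
  tracks <- list()
  active <- integer(0)      # indices into tracks
  new_track <- function(f, i, tab) {
    list(id = length(tracks) + 1L, frames = f, det = i,
         row = tab$centroid_row[i], col = tab$centroid_col[i],
         area_um2 = tab$area_um2[i])
  }
  tab1 <- frames[[1]]$table
  for (i in seq_len(nrow(tab1))) {
    tracks[[length(tracks) + 1L]] <- new_track(1L, i, tab1)
    active <- c(active, length(tracks))
  }
  big <- 1e8
  for (f in seq_along(frames)[-1]) {
    tab <- frames[[f]]$table
    nd <- nrow(tab)
    n_act <- length(active)
    assigned_det <- rep(FALSE, nd)
    matched_trk <- rep(FALSE, n_act)
    if (n_act > 0 && nd > 0) {
      last_r <- vapply(active, function(t) tail(tracks[[t]]$row, 1), 0)
      last_c <- vapply(active, function(t) tail(tracks[[t]]$col, 1), 0)
      last_f <- vapply(active, function(t) tail(tracks[[t]]$frames, 1), 0L)
      gate_px <- (f - last_f) * max_displacement_um / pixel_size_um
      cost <- matrix(big, n_act, nd)
      for (a in seq_len(n_act)) {
        d <- sqrt((tab$centroid_row - last_r[a])^2 +
                    (tab$centroid_col - last_c[a])^2)
        ok <- d <= gate_px[a]
        cost[a, ok] <- d[ok]
      }
      sol <- .assign_min_cost(cost, big)
      for (a in seq_len(n_act)) {
        j <- sol[a]
        if (!is.na(j) && cost[a, j] < big) {
          t <- active[a]
          tracks[[t]]$frames <- c(tracks[[t]]$frames, f)
          tracks[[t]]$det <- c(tracks[[t]]$det, j)
          tracks[[t]]$row <- c(tracks[[t]]$row, tab$centroid_row[j])
          tracks[[t]]$col <- c(tracks[[t]]$col, tab$centroid_col[j])
          tracks[[t]]$area_um2 <- c(tracks[[t]]$area_um2, tab$area_um2[j])
          assigned_det[j] <- TRUE
          matched_trk[a] <- TRUE
        }
      }
    }
    # drop tracks missing too long; annotate fusions
    still <- logical(length(active))
    for (a in seq_len(n_act)) {
      t <- active[a]
      if (matched_trk[a]) { still[a] <- TRUE; next }
      if (f - tail(tracks[[t]]$frames, 1) <= max_missing) {
        still[a] <- TRUE
        next
      }
      lr <- round(tail(tracks[[t]]$row, 1)); lc <- round(tail(tracks[[t]]$col, 1))
      lab <- frames[[f]]$labels
      if (lr >= 1 && lc >= 1 && lr <= nrow(lab) && lc <= ncol(lab) &&
          lab[lr, lc] > 0L)
        tracks[[t]]$fused_into <- as.integer(lab[lr, lc])
    }
    active <- active[still]
    if (nd > 0) for (j in which(!assigned_det)) {
      tracks[[length(tracks) + 1L]] <- new_track(f, j, tab)
      active <- c(active, length(tracks))
    }
  }
  .close_track_gaps(tracks, max_displacement_um / pixel_size_um,
                    max_missing + 2L)
}

# Exact minimum-cost assignment under a feasibility gate. The gated
# bipartite graph decomposes into small connected components (a droplet
# can only be confused with its immediate neighbours), so each component
# is solved by exhaustive enumeration maximising the number of matches
# and, among those, minimising total cost. Returns, per row, the matched
# column or NA.
.assign_min_cost <- function(cost, big) {
  n_r <- nrow(cost); n_c <- ncol(cost)
  res <- rep(NA_integer_, n_r)
  feas <- which(cost < big, arr.ind = TRUE)
  if (nrow(feas) == 0) return(res)
  # connected components over rows/cols via union-find
  parent <- seq_len(n_r + n_c)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (e in seq_len(nrow(feas))) {
    ra <- find(feas[e, 1]); cb <- find(n_r + feas[e, 2])
    if (ra != cb) parent[max(ra, cb)] <- min(ra, cb)
  }
  roots <- vapply(seq_len(n_r + n_c), find, integer(1))
  for (root in unique(roots[feas[, 1]])) {
    rows <- which(roots[seq_len(n_r)] == root)
    cols <- which(roots[n_r + seq_len(n_c)] == root)
    sub <- cost[rows, cols, drop = FALSE]
    if (length(rows) == 1L) {
      j <- which.min(sub[1, ])
      if (sub[1, j] < big) res[rows] <- cols[j]
      next
    }
    best <- NULL; best_key <- c(-Inf, Inf)   # (matches, -cost)
    assign_rec <- function(r, used, acc, nmatch, cur) {
      if (r > length(rows)) {
        if (nmatch > best_key[1] ||
            (nmatch == best_key[1] && acc < best_key[2])) {
          best_key <<- c(nmatch, acc)
          best <<- cur
        }
        return(invisible())
      }
      # bound: even matching all remaining rows cannot beat best
      if (nmatch + (length(rows) - r + 1) < best_key[1])
        return(invisible())
      for (j in seq_along(cols)) {
        if (used[j] || sub[r, j] >= big) next
        used[j] <- TRUE
        cur[r] <- j
        assign_rec(r + 1L, used, acc + sub[r, j], nmatch + 1L, cur)
        used[j] <- FALSE
        cur[r] <- NA_integer_
      }
      assign_rec(r + 1L, used, acc, nmatch, cur)
    }
    if (length(rows) <= 10L) {
      assign_rec(1L, rep(FALSE, length(cols)), 0, 0L,
                 rep(NA_integer_, length(rows)))
      if (!is.null(best))
        for (r in seq_along(rows))
          if (!is.na(best[r])) res[rows[r]] <- cols[best[r]]
    } else {
      # degenerate, very dense component: greedy by increasing cost
      ord <- order(sub)
      used_r <- rep(FALSE, length(rows)); used_c <- rep(FALSE, length(cols))
      for (o in ord) {
        if (sub[o] >= big) break
        r <- (o - 1) %% length(rows) + 1; j <- (o - 1) %/% length(rows) + 1
        if (used_r[r] || used_c[j]) next
        used_r[r] <- TRUE; used_c[j] <- TRUE
        res[rows[r]] <- cols[j]
      }
    }
  }
  res
}

# gap closing: stitch a track that ends to one that starts a few frames
# later at a nearby position (greedy, smallest displacement first), so a
# short detection dropout does not split an identity in two
.close_track_gaps <- function(tracks, max_disp_px, max_gap) {
  repeat {
    ends <- vapply(tracks, function(t) tail(t$frames, 1), 0L)
    starts <- vapply(tracks, function(t) t$frames[1], 0L)
    best <- NULL; best_d <- Inf
    for (a in seq_along(tracks)) {
      cand <- which(starts > ends[a] & starts - ends[a] <= max_gap)
      for (b in cand) {
        d <- sqrt((tail(tracks[[a]]$row, 1) - tracks[[b]]$row[1])^2 +
                    (tail(tracks[[a]]$col, 1) - tracks[[b]]$col[1])^2)
        if (d <= (starts[b] - ends[a]) * max_disp_px && d < best_d) {
          best <- c(a, b); best_d <- d
        }
      }
    }
    if (is.null(best)) break
    a <- best[1]; b <- best[2]
    for (fld in c("frames", "det", "row", "col", "area_um2"))
      tracks[[a]][[fld]] <- c(tracks[[a]][[fld]], tracks[[b]][[fld]])
    if (!is.null(tracks[[b]]$fused_into))
      tracks[[a]]$fused_into <- tracks[[b]]$fused_into
    tracks[[b]] <- NULL
  }
  for (t in seq_along(tracks)) tracks[[t]]$id <- t
  tracks
}

#' Per-frame association state of droplet pairs
#'
#' For every pair of tracks that is associated (boundary gap at most
#' \code{threshold_px}) in at least one common frame, records the state
#' in each frame where both are observed: \code{1} associated, \code{0}
#' dissociated. Frames where either track is unobserved are absent from
#' the series (state unknown).
#'
#' @param tracks output of \code{\link{track_droplets}}.
#' @param frames the list of \code{ld_droplets} used for tracking.
#' @param threshold_px association threshold on the boundary gap.
#' @param denoise apply a majority (median-of-3) filter to each state
#'   sequence? Single-frame flickers caused by boundary-pixel jitter are
#'   removed; genuine dissociations, which persist for several frames,
#'   are unaffected.
#' @return A list of series; each has \code{pair} (two track ids),
#'   \code{frames}, \code{state}, and per-frame centroid coordinates
#'   \code{r1,c1,r2,c2} (px).
#' @export
pair_state_series <- function(tracks, frames, threshold_px = 2,
                              denoise = FALSE) {
  n_frames <- length(frames)
  # per frame: which tracks observed, their detection index
  obs <- vector("list", n_frames)
  for (t in seq_along(tracks))
    for (k in seq_along(tracks[[t]]$frames)) {
      f <- tracks[[t]]$frames[k]
      obs[[f]] <- rbind(obs[[f]], c(t, tracks[[t]]$det[k]))
    }
  series <- new.env(parent = emptyenv())
  for (f in seq_len(n_frames)) {
    ob <- obs[[f]]
    if (is.null(ob) || nrow(ob) < 2) next
    dr <- frames[[f]]
    cen_r <- dr$table$centroid_row[ob[, 2]]
    cen_c <- dr$table$centroid_col[ob[, 2]]
    rmax <- vapply(ob[, 2], function(i) {
      b <- dr$boundary[[i]]
      if (nrow(b) == 0) b <- dr$px[[i]]
      sqrt(max((b[, 1] - dr$table$centroid_row[i])^2 +
                 (b[, 2] - dr$table$centroid_col[i])^2))
    }, 0)
    n <- nrow(ob)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d <- sqrt((cen_r[i] - cen_r[j])^2 + (cen_c[i] - cen_c[j])^2)
      if (d - rmax[i] - rmax[j] > 3 * threshold_px + 4) next
      gap <- boundary_gap(dr$boundary[[ob[i, 2]]], dr$boundary[[ob[j, 2]]])
      st <- as.integer(gap <= threshold_px)
      key <- paste(sort(c(tracks[[ob[i, 1]]]$id, tracks[[ob[j, 1]]]$id)),
                   collapse = ";")
      cur <- series[[key]]
      if (is.null(cur))
        cur <- list(pair = sort(c(tracks[[ob[i, 1]]]$id,
                                  tracks[[ob[j, 1]]]$id)),
                    frames = integer(0), state = integer(0),
                    r1 = numeric(0), c1 = numeric(0),
                    r2 = numeric(0), c2 = numeric(0))
      o <- order(c(tracks[[ob[i, 1]]]$id, tracks[[ob[j, 1]]]$id))
      rr <- c(cen_r[i], cen_r[j])[o]; cc <- c(cen_c[i], cen_c[j])[o]
      cur$frames <- c(cur$frames, f)
      cur$state <- c(cur$state, st)
      cur$r1 <- c(cur$r1, rr[1]); cur$c1 <- c(cur$c1, cc[1])
      cur$r2 <- c(cur$r2, rr[2]); cur$c2 <- c(cur$c2, cc[2])
      series[[key]] <- cur
    }
  }
  out <- as.list(series)
  if (denoise)
    out <- lapply(out, function(s) {
      n <- length(s$state)
      if (n >= 3) {
        sm <- s$state
        for (k in 2:(n - 1))
          sm[k] <- as.integer(s$state[k - 1] + s$state[k] +
                                s$state[k + 1] >= 2)
        s$state <- sm
      }
      s
    })
  out <- out[vapply(out, function(s) any(s$state == 1L), logical(1))]
  out <- unname(out)
  out[order(vapply(out, function(s) paste(sprintf("%06d", s$pair),
                                          collapse = ";"), character(1)))]
}

#' Classify an associated pair as static or dynamic over a window
#'
#' A pair that is associated at the start of the observation window and
#' stays associated in every observed frame of the window is static; a
#' pair that dissociates at least once is dynamic. Pairs never associated
#' should not be passed in (they belong to neither class).
#'
#' @param series one element of \code{\link{pair_state_series}}.
#' @param window_s window length in seconds (default 300, i.e. 5 min).
#' @param frame_interval_s seconds between frames (default 2).
#' @return A list with \code{class} ("static" or "dynamic") and
#'   \code{truncated} (\code{TRUE} when the series ends before the
#'   window does).
#' @export
classify_pair <- function(series, window_s = 300, frame_interval_s = 2) {
  n_window <- floor(window_s / frame_interval_s)
  sel <- series$frames <= n_window + 1L
  if (!any(sel)) stop("series has no frames inside the window")
  st <- series$state[sel]
  if (st[1] != 1L)
    stop("pair is not associated at the window start")
  truncated <- max(series$frames) < n_window + 1L
  list(class = if (all(st == 1L)) "static" else "dynamic",
       truncated = truncated)
}

#' Detect persistent dissociation events in pair state series
#'
#' An event is the first frame of an associated-to-dissociated transition
#' whose dissociated run lasts at least \code{persistence_frames}
#' observed frames, following an associated run of at least
#' \code{persistence_frames}. Re-association afterwards is allowed, so a
#' pair can contribute several events. The event site is the midpoint of
#' the two centroids at the last associated frame.
#'
#' @param series_list output of \code{\link{pair_state_series}}.
#' @param persistence_frames minimum run length (default 3).
#' @return data.frame: \code{pair_i}, \code{pair_j}, \code{t_event}
#'   (frame index of the first dissociated frame), \code{run_end} (last
#'   frame of the dissociated run), \code{site_row}, \code{site_col}.
#' @export
detect_dissociations <- function(series_list, persistence_frames = 3) {
  rows <- list()
  for (s in series_list) {
    st <- s$state
    n <- length(st)
    if (n < 2) next
    run_len <- function(from, value) {
      l <- 0L
      for (k in from:n) { if (st[k] != value) break; l <- l + 1L }
      l
    }
    k <- 1L
    assoc_run <- 0L
    while (k <= n) {
      if (st[k] == 1L) {
        assoc_run <- assoc_run + 1L
      } else {
        dlen <- run_len(k, 0L)
        if (assoc_run >= persistence_frames && dlen >= persistence_frames) {
          prev <- k - 1L
          rows[[length(rows) + 1L]] <- data.frame(
            pair_i = s$pair[1], pair_j = s$pair[2],
            t_event = s$frames[k],
            run_end = s$frames[k + dlen - 1L],
            site_row = (s$r1[prev] + s$r2[prev]) / 2,
            site_col = (s$c1[prev] + s$c2[prev]) / 2)
        }
        k <- k + dlen - 1L
        assoc_run <- 0L
      }
      k <- k + 1L
    }
  }
  if (length(rows) == 0)
    return(data.frame(pair_i = integer(0), pair_j = integer(0),
                      t_event = integer(0), run_end = integer(0),
                      site_row = numeric(0), site_col = numeric(0)))
  do.call(rbind, rows)
}

#' Score marker co-occurrence and timing at dissociation events
#'
#' For each event, the mean marker intensity in a disc of
#' \code{roi_radius_um} at the event site is followed from
#' \code{pre_window_frames} before the event to the end of the
#' dissociated run. The event is marker-positive when the ROI mean
#' exceeds the frame background mean plus three background standard
#' deviations (both estimated robustly per frame as median and
#' MAD x 1.4826) in any of those frames; the timing is "before" when the
#' first exceedance precedes the event frame, "during" otherwise.
#'
#' @param events data.frame from \code{\link{detect_dissociations}}.
#' @param marker_frames list of marker-channel matrices, registered with
#'   the LD channel.
#' @param roi_radius_um ROI radius (default 0.3 um).
#' @param pre_window_frames frames inspected before the event (default 5).
#' @param pixel_size_um calibration.
#' @return A list with \code{events} (input plus \code{marker_positive},
#'   \code{marker_timing}) and \code{summary} (fractions positive /
#'   before / during among positives).
#' @export
score_marker <- function(events, marker_frames, roi_radius_um = 0.3,
                         pre_window_frames = 5, pixel_size_um = 0.133) {
  n <- nrow(events)
  positive <- logical(n)
  timing <- rep("none", n)
  if (n > 0) {
    d1 <- dim(marker_frames[[1]])
    r_px <- roi_radius_um / pixel_size_um
    bg_mean <- vapply(marker_frames, median, 0)
    bg_sd <- vapply(marker_frames, mad, 0)
    for (e in seq_len(n)) {
      if (events$site_row[e] < 1 || events$site_row[e] > d1[1] ||
          events$site_col[e] < 1 || events$site_col[e] > d1[2])
        stop("event site outside the marker frame; channels unregistered?")
      roi <- .disc_pixels(events$site_row[e], events$site_col[e],
                          max(r_px, 1), d1[1], d1[2])
      f0 <- max(1L, events$t_event[e] - pre_window_frames)
      f1 <- min(length(marker_frames), events$run_end[e])
      for (f in f0:f1) {
        if (mean(marker_frames[[f]][roi]) > bg_mean[f] + 3 * bg_sd[f]) {
          positive[e] <- TRUE
          timing[e] <- if (f < events$t_event[e]) "before" else "during"
          break
        }
      }
    }
  }
  events$marker_positive <- positive
  events$marker_timing <- timing
  pos <- sum(positive)
  list(events = events,
       summary = c(fraction_positive = if (n) pos / n else NA_real_,
                   fraction_before = if (pos) sum(timing == "before") / pos
                                     else NA_real_,
                   fraction_during = if (pos) sum(timing == "during") / pos
                                     else NA_real_))
}

#' Intensity line profile between two points
#'
#' Bilinearly interpolated intensities at \code{n_samples} equally spaced
#' points on the segment from \code{p0} to \code{p1} (both \code{(row,
#' col)} in pixels), as used to visualise marker accumulation between
#' dissociating droplets.
#'
#' @param image 2D numeric matrix.
#' @param p0,p1 numeric length-2 endpoints, inside the image.
#' @param n_samples number of samples (default 50).
#' @param pixel_size_um calibration for the returned positions.
#' @return data.frame with \code{position_um} (distance from \code{p0})
#'   and \code{intensity}.
#' @export
line_profile <- function(image, p0, p1, n_samples = 50,
                         pixel_size_um = 0.133) {
  stopifnot(length(p0) == 2, length(p1) == 2, n_samples >= 2)
  inb <- function(p) p[1] >= 1 && p[1] <= nrow(image) &&
    p[2] >= 1 && p[2] <= ncol(image)
  if (!inb(p0) || !inb(p1)) stop("profile endpoints outside the image")
  tt <- seq(0, 1, length.out = n_samples)
  rows <- p0[1] + tt * (p1[1] - p0[1])
  cols <- p0[2] + tt * (p1[2] - p0[2])
  data.frame(position_um = tt * sqrt(sum((p1 - p0)^2)) * pixel_size_um,
             intensity = .bilinear_sample(image, rows, cols))
}
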