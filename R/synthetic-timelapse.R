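#' Generate a synthetic time-lapse of droplet pairs with planted kinetics
#'
#' Plants \code{n_pairs} droplet pairs on a jittered grid. Each pair
#' switches between an associated state (boundary gap of one background
#' pixel, i.e. 2 px between pixel centres) and a dissociated state
#' (boundary gap \code{separation_px}) as a two-state Markov process in
#' continuous time with rates \code{k_dissoc} and \code{k_assoc},
#' sampled at the frame interval; all pairs start associated. While
#' associated a pair may also fuse (rate \code{k_fuse}), after which it
#' is rendered as one droplet of summed area and produces no further
#' events. Each dissociation is marker-positive with probability
#' \code{marker_positive_fraction}; positive events receive a
#' diffraction-limited marker focus at the pair midpoint whose onset is
#' "before" (appearing \code{marker_lead_frames} frames before the
#' separation) with probability \code{marker_before_fraction}, otherwise
#' "during" (appearing at the first separated frame). The emulation is a
#' validation harness for the dynamics pipeline: it reproduces the
#' sampling structure of live imaging (5-min recordings at 2-s
#' intervals), not the physics of droplet motion.
#'
#' @param spec a \code{\link{field_spec}}; supplies frame geometry, the
#'   droplet area distribution, calibration, SNR and PSF width.
#' @param duration_s total duration (default 300 s).
#' @param frame_interval_s frame spacing (default 2 s).
#' @param k_dissoc,k_assoc,k_fuse transition rates per second.
#' @param marker_positive_fraction probability a dissociation is
#'   accompanied by a marker focus.
#' @param marker_before_fraction probability a positive event has its
#'   marker onset before the separation.
#' @param marker_lead_frames onset lead of "before" markers, in frames.
#' @param n_pairs number of planted pairs.
#' @param separation_px boundary gap of the dissociated state (px).
#' @param render_marker render the marker channel? Disable for kinetic
#'   validations that do not score markers.
#' @param seed random seed; defaults to \code{spec$seed}.
#' @return A list with \code{ld_frames} (list of matrices),
#'   \code{marker_frames} (list of matrices), \code{truth} (list:
#'   \code{pair_table}, \code{event_log}, \code{state} matrix of 0/1/2 =
#'   dissociated/associated/fused per pair x frame), and the time axis
#'   \code{time_s}.
#' @export
generate_timelapse <- function(spec, duration_s = 300, frame_interval_s = 2,
                               k_dissoc = 0.005, k_assoc = 0.005,
                               k_fuse = 0,
                               marker_positive_fraction = 0.6,
                               marker_before_fraction = 0.7,
                               marker_lead_frames = 3,
                               n_pairs = 20,
                               separation_px = 10,
                               render_marker = TRUE,
                               seed = spec$seed) {
  stopifnot(inherits(spec, "field_spec"),
            duration_s >= frame_interval_s, frame_interval_s > 0,
            k_dissoc >= 0, k_assoc >= 0, k_fuse >= 0,
            marker_positive_fraction >= 0, marker_positive_fraction <= 1,
            marker_before_fraction >= 0, marker_before_fraction <= 1,
            n_pairs >= 1, separation_px > 2)
  set.seed(seed)
  nr <- spec$height_px; nc <- spec$width_px
  n_frames <- floor(duration_s / frame_interval_s) + 1L
  time_s <- (seq_len(n_frames) - 1L) * frame_interval_s
  geom <- .place_pairs(spec, n_pairs, separation_px, nr, nc)
  sim <- .simulate_pair_kinetics(n_pairs, duration_s, frame_interval_s,
                                 k_dissoc, k_assoc, k_fuse,
                                 marker_positive_fraction,
                                 marker_before_fraction,
                                 marker_lead_frames)
  ld_frames <- vector("list", n_frames)
  marker_frames <- vector("list", n_frames)
  # pairs never overlap, so each pair's three possible rasterisations are
  # pre-blurred once as local patches and composed per frame
  patch_of <- function(px, extra = NULL) {
    r0 <- max(1L, min(px[, 1]) - 6L); r1b <- min(nr, max(px[, 1]) + 6L)
    c0 <- max(1L, min(px[, 2]) - 6L); c1b <- min(nc, max(px[, 2]) + 6L)
    w <- matrix(0, r1b - r0 + 1L, c1b - c0 + 1L)
    w[cbind(px[, 1] - r0 + 1L, px[, 2] - c0 + 1L)] <- 1
    if (spec$psf_sigma_px > 0) w <- EBImage::gblur(w, spec$psf_sigma_px)
    keep <- which(w > 0)
    co <- arrayInd(keep, dim(w))
    list(idx = cbind(co[, 1] + r0 - 1L, co[, 2] + c0 - 1L), val = w[keep])
  }
  cache <- lapply(geom, function(g) list(
    assoc = patch_of(rbind(.offset_disc(g, g$d_assoc, g$r1, -1, nr, nc),
                           .offset_disc(g, g$d_assoc, g$r2, +1, nr, nc))),
    sep = patch_of(rbind(.offset_disc(g, g$d_sep, g$r1, -1, nr, nc),
                         .offset_disc(g, g$d_sep, g$r2, +1, nr, nc))),
    fused = patch_of(.disc_pixels(g$row, g$col, sqrt(g$r1^2 + g$r2^2),
                                  nr, nc))))
  mk_patch <- lapply(geom, function(g) {
    rr <- max(1, floor(g$row - 6)):min(nr, ceiling(g$row + 6))
    cc <- max(1, floor(g$col - 6)):min(nc, ceiling(g$col + 6))
    w <- outer(exp(-(rr - g$row)^2 / (2 * 1.5^2)),
               exp(-(cc - g$col)^2 / (2 * 1.5^2)))
    if (spec$psf_sigma_px > 0) w <- EBImage::gblur(w, spec$psf_sigma_px)
    keep <- which(w > 1e-4)
    co <- arrayInd(keep, dim(w))
    list(idx = cbind(co[, 1] + rr[1] - 1L, co[, 2] + cc[1] - 1L),
         val = w[keep])
  })
  # marker visibility window per positive dissociation: onset to run end
  ev <- sim$event_log
  for (f in seq_len(n_frames)) {
    ld <- matrix(0, nr, nc)
    mk <- matrix(0, nr, nc)
    for (p in seq_len(n_pairs)) {
      pt <- switch(sim$state[p, f] + 1L, cache[[p]]$sep, cache[[p]]$assoc,
                   cache[[p]]$fused)
      ld[pt$idx] <- pt$val
    }
    if (render_marker && nrow(ev)) {
      vis <- ev$marker_positive & f >= ev$marker_on & f <= ev$marker_off
      for (e in which(vis)) {
        pt <- mk_patch[[ev$pair_id[e]]]
        mk[pt$idx] <- mk[pt$idx] + pt$val
      }
    }
    ld_frames[[f]] <- .apply_noise(ld, spec$snr)
    if (render_marker)
      marker_frames[[f]] <- .apply_noise(mk, spec$snr)
  }
  if (!render_marker) marker_frames <- NULL
  pair_table <- data.frame(
    pair_id = seq_len(n_pairs),
    row = vapply(geom, function(g) g$row, 0),
    col = vapply(geom, function(g) g$col, 0),
    r1_px = vapply(geom, function(g) g$r1, 0),
    r2_px = vapply(geom, function(g) g$r2, 0))
  list(ld_frames = ld_frames, marker_frames = marker_frames,
       truth = list(pair_table = pair_table, event_log = sim$event_log,
                    state = sim$state),
       time_s = time_s,
       pixel_size_um = spec$pixel_size_um,
       frame_interval_s = frame_interval_s)
}

# place pair anchors on a jittered grid; orientation random; the
# associated-state centre offset is tuned so the rasterised pixel gap is
# exactly 2 px (one background pixel), the dissociated offset gives a gap
# of separation_px
.place_pairs <- function(spec, n_pairs, separation_px, nr, nc) {
  dist <- spec$ld_area_um2_distribution
  px_area <- spec$pixel_size_um^2
  # resolvable radii: the dynamics harness targets droplets large enough
  # to track individually yet small enough that an associated pair shows
  # a clear intensity valley
  r_all <- sqrt(pmin(pmax(rlnorm(2 * n_pairs, dist$meanlog, dist$sdlog),
                          0.15), 0.9) / px_area / pi)
  r1 <- r_all[seq_len(n_pairs)]
  r2 <- r_all[n_pairs + seq_len(n_pairs)]
  rmax <- max(r1, r2)
  # neighbouring pairs must stay clearly dissociated from one another
  # even when both are in the separated state
  pitch <- ceiling(4 * rmax + separation_px + 10)
  n_col <- max(1L, floor((nc - pitch) / pitch))
  n_row <- ceiling(n_pairs / n_col)
  if (n_row * pitch + pitch > nr)
    .placement_fail(sprintf("%d droplet pairs (pitch %d px)", n_pairs,
                            pitch), 1L)
  geom <- vector("list", n_pairs)
  for (p in seq_len(n_pairs)) {
    gi <- (p - 1L) %/% n_col; gj <- (p - 1L) %% n_col
    # find a sub-pixel position, orientation and associated-state centre
    # distance whose rasterised pixel gap is exactly 2.0 (some
    # orientations admit none) and whose rendered pair is optically
    # resolvable: the clean blurred bridge between the droplets must stay
    # below the half-maximum of the dimmer one, else the detector cannot
    # separate the pair in any frame
    d_assoc <- NA_real_
    u <- c(1, 0)
    row <- col <- 0
    for (att in 1:400) {
      row <- pitch / 2 + pitch * gi + pitch / 2 + runif(1, -2, 2)
      col <- pitch / 2 + pitch * gj + pitch / 2 + runif(1, -2, 2)
      theta <- runif(1, 0, pi)
      uu <- c(cos(theta), sin(theta))
      for (dd in seq(r1[p] + r2[p] + 0.6, r1[p] + r2[p] + 3.2, by = 0.05)) {
        p1 <- .disc_pixels(row - uu[1] * dd / 2, col - uu[2] * dd / 2,
                           r1[p], nr, nc)
        p2 <- .disc_pixels(row + uu[1] * dd / 2, col + uu[2] * dd / 2,
                           r2[p], nr, nc)
        if (is.null(p1) || is.null(p2) || nrow(p1) == 0 || nrow(p2) == 0)
          next
        if (abs(.min_cross_dist(p1, p2) - 2) >= 1e-9) next
        if (!.pair_resolvable(p1, p2, spec$psf_sigma_px,
                              row, col, uu, dd, nr, nc)) next
        d_assoc <- dd
        u <- uu
        break
      }
      if (!is.na(d_assoc)) break
    }
    if (is.na(d_assoc))
      .placement_fail(sprintf("pair %d in the associated state", p), 400L)
    geom[[p]] <- list(row = row, col = col, u = u, r1 = r1[p], r2 = r2[p],
                      d_assoc = d_assoc,
                      d_sep = r1[p] + r2[p] + separation_px)
  }
  geom
}

# noise-free resolvability check of a candidate associated pair: render
# both discs in a local window, blur with the PSF, and require the
# valley between the two centres to sit below 0.45 x the dimmer peak
.pair_resolvable <- function(p1, p2, psf_sigma, row, col, u, dd, nr, nc) {
  all_px <- rbind(p1, p2)
  r0 <- max(1L, min(all_px[, 1]) - 6L); r1b <- min(nr, max(all_px[, 1]) + 6L)
  c0 <- max(1L, min(all_px[, 2]) - 6L); c1b <- min(nc, max(all_px[, 2]) + 6L)
  w <- matrix(0, r1b - r0 + 1L, c1b - c0 + 1L)
  w[cbind(all_px[, 1] - r0 + 1L, all_px[, 2] - c0 + 1L)] <- 1
  if (psf_sigma > 0) w <- EBImage::gblur(w, sigma = psf_sigma)
  ctr1 <- c(row - u[1] * dd / 2 - r0 + 1, col - u[2] * dd / 2 - c0 + 1)
  ctr2 <- c(row + u[1] * dd / 2 - r0 + 1, col + u[2] * dd / 2 - c0 + 1)
  ns <- max(5L, ceiling(2 * dd))
  prof <- .bilinear_sample(w, seq(ctr1[1], ctr2[1], length.out = ns),
                           seq(ctr1[2], ctr2[2], length.out = ns))
  pk1 <- max(prof[seq_len(floor(ns / 3))])
  pk2 <- max(prof[(ns - floor(ns / 3)):ns])
  mid <- min(prof[(floor(ns / 3)):(ns - floor(ns / 3))])
  mid < 0.45 * min(pk1, pk2)
}

.offset_disc <- function(g, d, r, sign, nr, nc) {
  .disc_pixels(g$row + sign * g$u[1] * d / 2,
               g$col + sign * g$u[2] * d / 2, r, nr, nc)
}

# exact continuous-time simulation of the two-state (plus absorbing
# fused) chain, sampled at the frame grid
.simulate_pair_kinetics <- function(n_pairs, duration_s, frame_interval_s,
                                    k_dissoc, k_assoc, k_fuse,
                                    p_marker, p_before, lead_frames) {
  n_frames <- floor(duration_s / frame_interval_s) + 1L
  state <- matrix(1L, n_pairs, n_frames)   # start associated
  rows <- list()
  frame_of <- function(t) floor(t / frame_interval_s) + 1L
  for (p in seq_len(n_pairs)) {
    t <- 0; s <- 1L
    while (t < duration_s) {
      if (s == 1L) {
        rate_total <- k_dissoc + k_fuse
        if (rate_total <= 0) break
        dt <- rexp(1, rate_total)
        t2 <- t + dt
        if (t2 >= duration_s) break
        fuse <- runif(1) < k_fuse / rate_total
        f2 <- frame_of(t2)
        if (fuse) {
          state[p, (f2 + 1L):n_frames] <- 2L
          rows[[length(rows) + 1L]] <- data.frame(
            time_s = t2, frame = f2 + 1L, pair_id = p, event = "fuse",
            marker_positive = FALSE, marker_onset = NA_character_,
            marker_on = NA_integer_, marker_off = NA_integer_)
          break
        }
        s <- 0L
        if (f2 + 1L <= n_frames) state[p, (f2 + 1L):n_frames] <- 0L
        mk <- runif(1) < p_marker
        onset <- if (mk && runif(1) < p_before) "before" else
                 if (mk) "during" else NA_character_
        rows[[length(rows) + 1L]] <- data.frame(
          time_s = t2, frame = f2 + 1L, pair_id = p, event = "dissociate",
          marker_positive = mk, marker_onset = onset,
          marker_on = NA_integer_, marker_off = NA_integer_)
        t <- t2
      } else {
        if (k_assoc <= 0) break
        dt <- rexp(1, k_assoc)
        t2 <- t + dt
        if (t2 >= duration_s) break
        f2 <- frame_of(t2)
        s <- 1L
        if (f2 + 1L <= n_frames) state[p, (f2 + 1L):n_frames] <- 1L
        rows[[length(rows) + 1L]] <- data.frame(
          time_s = t2, frame = f2 + 1L, pair_id = p, event = "associate",
          marker_positive = FALSE, marker_onset = NA_character_,
          marker_on = NA_integer_, marker_off = NA_integer_)
        t <- t2
      }
    }
  }
  ev <- if (length(rows)) do.call(rbind, rows) else
    data.frame(time_s = numeric(0), frame = integer(0),
               pair_id = integer(0), event = character(0),
               marker_positive = logical(0), marker_onset = character(0),
               marker_on = integer(0), marker_off = integer(0))
  # marker visibility windows: from onset to the end of the dissociated run
  if (nrow(ev)) {
    for (e in which(ev$event == "dissociate" & ev$marker_positive)) {
      p <- ev$pair_id[e]; f0 <- ev$frame[e]
      run <- f0
      while (run < n_frames && state[p, run + 1L] == 0L) run <- run + 1L
      ev$marker_on[e] <- if (ev$marker_onset[e] == "before")
        max(1L, f0 - lead_frames) else f0
      ev$marker_off[e] <- run
    }
  }
  list(state = state, event_log = ev)
}
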