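# build a list of per-frame droplet sets from planted disc positions:
# positions[[f]] is a matrix with one row (row, col, r) per droplet
frames_from_discs <- function(positions, dim = 80) {
  lapply(positions, function(pos) {
    labels <- matrix(0L, dim, dim)
    for (k in seq_len(nrow(pos)))
      labels[lipodrop:::.disc_pixels(pos[k, 1], pos[k, 2], pos[k, 3],
                                     dim, dim)] <- k
    droplet_records(labels, NULL, 0.133)
  })
}

test_that("tracking keeps stationary and slowly moving identities", {
  # one stationary droplet over 10 frames
  frames <- frames_from_discs(replicate(10, cbind(40, 40, 3),
                                        simplify = FALSE))
  tr <- track_droplets(frames)
  expect_equal(length(tr), 1L)
  expect_equal(length(tr[[1]]$frames), 10L)

  # two droplets 5 um apart, each drifting 0.1 um/frame: no identity swaps
  pos <- lapply(0:9, function(f)
    rbind(c(20 + f * 0.75, 20, 2.5),
          c(57, 57 + f * 0.75, 2.5)))
  tr2 <- track_droplets(frames_from_discs(pos))
  expect_equal(length(tr2), 2L)
  expect_true(all(vapply(tr2, function(t) length(t$frames), 0L) == 10L))
  # the track that started at (20,20) ends lower-right of its start only
  # in row
  t1 <- tr2[[which(vapply(tr2, function(t) t$row[1] < 30, logical(1)))]]
  expect_gt(tail(t1$row, 1), t1$row[1] + 5)
  expect_lt(abs(tail(t1$col, 1) - t1$col[1]), 1)
})

test_that("long disappearances split tracks; short gaps are closed", {
  # droplet absent for more frames than max_missing: two tracks
  pos <- c(replicate(4, cbind(40, 40, 3), simplify = FALSE),
           replicate(4, cbind(40, 40, 0.0), simplify = FALSE),  # absent
           replicate(4, cbind(40, 40, 3), simplify = FALSE))
  frames <- lapply(pos, function(p) {
    labels <- matrix(0L, 80, 80)
    if (p[1, 3] > 1) labels[lipodrop:::.disc_pixels(p[1, 1], p[1, 2],
                                                    p[1, 3], 80, 80)] <- 1L
    droplet_records(labels, NULL, 0.133)
  })
  tr <- track_droplets(frames, max_missing = 1)
  expect_equal(length(tr), 2L)
  # with a tolerant gap budget the identity is stitched back together
  tr2 <- track_droplets(frames, max_missing = 4)
  expect_equal(length(tr2), 1L)
})

test_that("every detection belongs to exactly one track", {
  set.seed(81)
  pos <- lapply(1:8, function(f) {
    cbind(c(20, 30, 60) + rnorm(3, 0, 0.3),
          c(20, 55, 40) + rnorm(3, 0, 0.3), 2.5)
  })
  frames <- frames_from_discs(pos)
  tr <- track_droplets(frames)
  seen <- matrix(0L, 8, 3)
  for (t in tr)
    for (k in seq_along(t$frames))
      seen[t$frames[k], t$det[k]] <- seen[t$frames[k], t$det[k]] + 1L
  expect_true(all(seen == 1L))
})

test_that("pair classification follows the every-frame rule", {
  mk_series <- function(states) list(pair = c(1, 2),
                                     frames = seq_along(states),
                                     state = states,
                                     r1 = rep(1, length(states)),
                                     c1 = rep(1, length(states)),
                                     r2 = rep(2, length(states)),
                                     c2 = rep(2, length(states)))
  all_on <- mk_series(rep(1L, 151))
  expect_equal(classify_pair(all_on)$class, "static")
  expect_false(classify_pair(all_on)$truncated)
  blip <- mk_series(c(rep(1L, 60), rep(0L, 10), rep(1L, 80)))
  expect_equal(classify_pair(blip)$class, "dynamic")
  short <- mk_series(rep(1L, 50))
  cs <- classify_pair(short)
  expect_equal(cs$class, "static")
  expect_true(cs$truncated)
  expect_error(classify_pair(mk_series(c(0L, 1L))), "not associated")
})

test_that("dissociation events count persistent runs only", {
  mk_series <- function(states) list(pair = c(1, 2),
                                     frames = seq_along(states),
                                     state = states,
                                     r1 = rep(10, length(states)),
                                     c1 = rep(10, length(states)),
                                     r2 = rep(16, length(states)),
                                     c2 = rep(10, length(states)))
  # no transitions: no events
  expect_equal(nrow(detect_dissociations(list(mk_series(rep(1L, 40))), 3)),
               0L)
  # associated 20, dissociated 10, re-associated 10, dissociated 10: 2
  st <- c(rep(1L, 20), rep(0L, 10), rep(1L, 10), rep(0L, 10))
  ev <- detect_dissociations(list(mk_series(st)), 3)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$t_event, c(21L, 41L))
  expect_equal(ev$site_row, c(13, 13))
  # a 2-frame dip is below persistence
  st2 <- c(rep(1L, 20), 0L, 0L, rep(1L, 20))
  expect_equal(nrow(detect_dissociations(list(mk_series(st2)), 3)), 0L)
  # a short associated prefix does not qualify
  st3 <- c(1L, rep(0L, 10), rep(1L, 10))
  expect_equal(nrow(detect_dissociations(list(mk_series(st3)), 3)), 0L)
})

test_that("marker scoring applies the 3-sigma ROI rule with timing", {
  ev <- data.frame(pair_i = 1, pair_j = 2, t_event = 10L, run_end = 20L,
                   site_row = 25, site_col = 25)
  set.seed(82)
  zero_frames <- replicate(25, matrix(rnorm(50 * 50, 100, 5), 50, 50),
                           simplify = FALSE)
  sc0 <- score_marker(ev, zero_frames, pixel_size_um = 0.133)
  expect_false(sc0$events$marker_positive)
  expect_equal(sc0$events$marker_timing, "none")
  expect_equal(unname(sc0$summary["fraction_positive"]), 0)

  # a focus present from t_event - 3 onward: positive, "before"
  spot_frames <- zero_frames
  for (f in 7:20) spot_frames[[f]][23:27, 23:27] <-
      spot_frames[[f]][23:27, 23:27] + 60
  scb <- score_marker(ev, spot_frames, pixel_size_um = 0.133)
  expect_true(scb$events$marker_positive)
  expect_equal(scb$events$marker_timing, "before")

  # onset at the event frame: "during"
  dur_frames <- zero_frames
  for (f in 10:20) dur_frames[[f]][23:27, 23:27] <-
      dur_frames[[f]][23:27, 23:27] + 60
  scd <- score_marker(ev, dur_frames, pixel_size_um = 0.133)
  expect_equal(scd$events$marker_timing, "during")
})

test_that("line profiles interpolate bilinearly with physical positions", {
  expect_equal(line_profile(matrix(4, 20, 20), c(3, 3), c(15, 15),
                            n_samples = 10)$intensity, rep(4, 10))
  ramp <- matrix(rep(1:30, each = 20), 20, 30)
  pr <- line_profile(ramp, c(10, 5), c(10, 25), n_samples = 21)
  expect_equal(pr$intensity, seq(5, 25, length.out = 21))
  expect_equal(max(pr$position_um), 20 * 0.133)
  # peak of a planted gaussian lands at the centre sample
  g <- outer(exp(-((1:40) - 20)^2 / 8), exp(-((1:40) - 24)^2 / 8))
  pg <- line_profile(g, c(20, 4), c(20, 39), n_samples = 36)
  expect_lt(abs(pg$position_um[which.max(pg$intensity)] - 20 * 0.133),
            1.01 * 0.133)
  expect_error(line_profile(ramp, c(0, 5), c(10, 25)), "outside")
})

test_that("a zero-rate time-lapse yields only static pairs and no events", {
  sp <- field_spec(width_px = 200, height_px = 200, seed = 83)
  tl <- generate_timelapse(sp, duration_s = 80, frame_interval_s = 2,
                           k_dissoc = 0, k_assoc = 0, n_pairs = 6,
                           render_marker = FALSE, seed = 83)
  cfg <- pipeline_config(output_dir = withr::local_tempdir(),
                         detection_method = "threshold", window_s = 80,
                         seed = 83)
  res <- suppressMessages(run_dynamics(cfg, tl$ld_frames))
  expect_equal(unname(res$summary["static_fraction"]), 1)
  expect_equal(unname(res$summary["n_events"]), 0)
  expect_equal(nrow(res$pairs), 6L)
})

test_that("requesting marker scoring without a channel is an error", {
  sp <- field_spec(width_px = 200, height_px = 200, seed = 84)
  tl <- generate_timelapse(sp, duration_s = 20, frame_interval_s = 2,
                           n_pairs = 4, render_marker = FALSE, seed = 84)
  cfg <- pipeline_config(output_dir = withr::local_tempdir(), seed = 84)
  expect_error(suppressMessages(
    run_dynamics(cfg, tl$ld_frames, score_markers = TRUE)),
    "no marker channel")
})
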