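test_that("the same spec and seed reproduce a field bit-identically", {
  sp <- small_field_spec(seed = 51)
  a <- generate_field(sp)
  b <- generate_field(sp)
  expect_identical(a$image$channels, b$image$channels)
  expect_identical(a$truth$ld_masks, b$truth$ld_masks)
  expect_identical(a$truth$planted_clusters, b$truth$planted_clusters)
})

test_that("noise-free, blur-free rendering reproduces the planted masks", {
  sp <- small_field_spec(seed = 52, snr = Inf, psf_sigma_px = 0)
  fg <- generate_field(sp)
  for (ch in c("nuclei", "cytoplasm", "ld")) {
    mask_true <- switch(ch, nuclei = fg$truth$nucleus_masks,
                        cytoplasm = fg$truth$cell_masks,
                        ld = fg$truth$ld_masks) > 0L
    fgmax <- max(fg$image$channels[[ch]])
    expect_identical(fg$image$channels[[ch]] > fgmax / 2, mask_true)
  }
})

test_that("planted clusters equal the brute-force gap oracle on true masks", {
  sp <- field_spec(width_px = 480, height_px = 480, n_cells = 1,
                   ld_count_per_cell = list(mean = 40),
                   cluster_fraction = 0.5, seed = 53)
  fg <- generate_field(sp)
  tr <- fg$truth
  px <- lapply(seq_len(nrow(tr$ld_table)), function(k) {
    idx <- which(tr$ld_masks == k)
    arrayInd(idx, dim(tr$ld_masks))
  })
  want <- oracle_clusters(px, 2)
  expect_identical(partition_key(lapply(tr$planted_clusters, sort)),
                   partition_key(want))
})

test_that("the noise model hits the specified background s.d.", {
  set.seed(54)
  for (snr in c(5, 10)) {
    blank <- lipodrop:::.apply_noise(matrix(0, 512, 512), snr)
    expect_lt(abs(sd(blank) - sqrt(100 + 9)) / sqrt(109), 0.1)
  }
})

test_that("impossible geometry fails with an explicit constraint message", {
  sp <- field_spec(width_px = 150, height_px = 150, n_cells = 6, seed = 55)
  expect_error(generate_field(sp), "geometric infeasibility")
})

test_that("a synthetic field and its truth round-trip through disk", {
  sp <- field_spec(width_px = 320, height_px = 320, n_cells = 1,
                   nucleus_diameter_px_range = c(90, 100),
                   ld_count_per_cell = list(mean = 15), seed = 56)
  fg <- generate_field(sp)
  dir <- withr::local_tempdir()
  paths <- write_synthetic_field(fg, dir)
  expect_identical(read_label_map(paths["lds"]), fg$truth$ld_masks)
  tr <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_equal(tr$ld_areas_um2, fg$truth$ld_areas_um2, tolerance = 1e-9)
})

test_that("time-lapse generation is deterministic and respects rate limits", {
  sp <- field_spec(width_px = 200, height_px = 200, seed = 57)
  a <- generate_timelapse(sp, duration_s = 60, frame_interval_s = 2,
                          k_dissoc = 0.01, k_assoc = 0.01, n_pairs = 6,
                          seed = 57)
  b <- generate_timelapse(sp, duration_s = 60, frame_interval_s = 2,
                          k_dissoc = 0.01, k_assoc = 0.01, n_pairs = 6,
                          seed = 57)
  expect_identical(a$ld_frames, b$ld_frames)
  expect_identical(a$truth$event_log, b$truth$event_log)

  # zero dissociation rate: no events, associated throughout
  z <- generate_timelapse(sp, duration_s = 60, frame_interval_s = 2,
                          k_dissoc = 0, k_assoc = 0, n_pairs = 6,
                          render_marker = FALSE, seed = 58)
  expect_equal(nrow(z$truth$event_log), 0L)
  expect_true(all(z$truth$state == 1L))

  # absorbing limit: k_assoc = 0, long duration -> every pair dissociates
  # exactly once
  ab <- generate_timelapse(sp, duration_s = 3000, frame_interval_s = 50,
                           k_dissoc = 0.01, k_assoc = 0, n_pairs = 6,
                           render_marker = FALSE, seed = 59)
  ev <- ab$truth$event_log
  expect_true(all(ev$event == "dissociate"))
  expect_equal(sort(unique(ev$pair_id)), 1:6)
  expect_equal(nrow(ev), 6L)
})

test_that("event log times are ordered within each pair and the duration", {
  sp <- field_spec(width_px = 200, height_px = 200, seed = 60)
  tl <- generate_timelapse(sp, duration_s = 120, frame_interval_s = 2,
                           k_dissoc = 0.02, k_assoc = 0.02, n_pairs = 6,
                           render_marker = FALSE, seed = 60)
  ev <- tl$truth$event_log
  expect_true(all(ev$time_s > 0 & ev$time_s < 120))
  for (p in unique(ev$pair_id)) {
    tp <- ev$time_s[ev$pair_id == p]
    expect_true(all(diff(tp) > 0))
  }
})

test_that("marker positivity follows the requested fraction", {
  sp <- field_spec(width_px = 660, height_px = 660, seed = 61)
  tl <- generate_timelapse(sp, duration_s = 300, frame_interval_s = 2,
                           k_dissoc = 5 * log(2) / 150, k_assoc = 0,
                           marker_positive_fraction = 0.6, n_pairs = 200,
                           render_marker = FALSE, seed = 61)
  ev <- tl$truth$event_log[tl$truth$event_log$event == "dissociate", ]
  expect_gte(nrow(ev), 150)
  p_hat <- mean(ev$marker_positive)
  ci <- 1.96 * sqrt(0.6 * 0.4 / nrow(ev))
  expect_lt(abs(p_hat - 0.6), ci + 1e-9)
})

test_that("fusion conserves planted droplet area up to rasterisation", {
  # the fused disc replaces the pair with one droplet of summed area
  set.seed(62)
  for (rep in 1:20) {
    r1 <- runif(1, 1.5, 4); r2 <- runif(1, 1.5, 4)
    a1 <- nrow(lipodrop:::.disc_pixels(50.3, 50.7, r1, 100, 100))
    a2 <- nrow(lipodrop:::.disc_pixels(50.1, 70.2, r2, 100, 100))
    af <- nrow(lipodrop:::.disc_pixels(50.5, 60.1, sqrt(r1^2 + r2^2),
                                       100, 100))
    expect_lt(abs(af - (a1 + a2)) / (a1 + a2), 0.15)
  }
  # and a rendered fuse event shows a single droplet of summed area
  sp <- field_spec(width_px = 200, height_px = 200, seed = 63)
  tl <- generate_timelapse(sp, duration_s = 100, frame_interval_s = 2,
                           k_dissoc = 0, k_assoc = 0, k_fuse = 0.05,
                           n_pairs = 4, render_marker = FALSE, seed = 63)
  ev <- tl$truth$event_log
  expect_true(all(ev$event == "fuse"))
  expect_gte(nrow(ev), 1)
})
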