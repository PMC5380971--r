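noisy <- function(clean, snr) lipodrop:::.apply_noise(clean, snr)

test_that("nucleus segmentation finds planted nuclei and sizes the gate", {
  expect_identical(segment_nuclei(matrix(0, 300, 300)),
                   matrix(0L, 300, 300))

  set.seed(21)
  img <- matrix(0, 420, 420)
  img <- paint_disc(img, 110, 120, 60)
  img <- paint_disc(img, 300, 290, 60)
  lab <- segment_nuclei(noisy(img, 10))
  expect_equal(max(lab), 2L)
  for (ctr in list(c(110, 120), c(300, 290))) {
    idx <- which(lab == lab[ctr[1], ctr[2]])
    co <- arrayInd(idx, dim(lab))
    expect_lt(sqrt(sum((colMeans(co) - ctr)^2)), 2)
  }
})

test_that("touching nuclei with an intensity valley are declumped", {
  # two radial intensity cones whose overlap leaves a ~33% valley between
  # the peaks
  n <- 360
  img <- matrix(0, n, n)
  cone <- function(img, cr, cc, r) {
    gr <- expand.grid(row = 1:n, col = 1:n)
    d <- sqrt((gr$row - cr)^2 + (gr$col - cc)^2)
    v <- pmax(1 - 0.4 * d / r, 0) * (d <= r)
    pmax(img, matrix(v, n, n))
  }
  img <- cone(img, 180, 130, 62)
  img <- cone(img, 180, 230, 62)
  lab <- segment_nuclei(noisy(img, 15))
  expect_equal(max(lab), 2L)
  expect_false(lab[180, 130] == lab[180, 230])
})

test_that("cell propagation covers the thresholded blob and splits at the midline", {
  # empty nuclei -> empty cells, no error
  expect_identical(segment_cells(matrix(1, 50, 50), matrix(0L, 50, 50)),
                   matrix(0L, 50, 50))

  # one nucleus inside one bright blob: the cell is the blob's
  # above-threshold support
  img <- matrix(0, 120, 120)
  img <- paint_disc(img, 60, 60, 40)
  nuc <- matrix(0L, 120, 120)
  nuc <- matrix(as.integer(paint_disc(matrix(0, 120, 120), 60, 60, 10)),
                120, 120)
  cells <- segment_cells(img, nuc)
  thr <- otsu_global(img)
  expect_identical(cells > 0L, img > thr)

  # two nuclei in one uniform blob: geodesic Voronoi oracle -- every
  # pixel away from the midline goes to its nearer seed
  img2 <- matrix(0, 120, 200)
  img2[20:100, 20:180] <- 1
  nuc2 <- matrix(0L, 120, 200)
  nuc2[55:65, 55:65] <- 1L
  nuc2[55:65, 135:145] <- 2L
  cells2 <- segment_cells(img2, nuc2)
  idx <- which(img2 > 0.5)
  co <- arrayInd(idx, dim(img2))
  d1 <- sqrt((co[, 1] - 60)^2 + (co[, 2] - 60)^2)
  d2 <- sqrt((co[, 1] - 60)^2 + (co[, 2] - 140)^2)
  clear <- abs(d1 - d2) > 3      # ignore pixels near the midline
  expect_true(all(cells2[idx][clear] == ifelse(d1 < d2, 1L, 2L)[clear]))
  # each cell contains its seed
  expect_true(all(cells2[nuc2 == 1L] == 1L))
  expect_true(all(cells2[nuc2 == 2L] == 2L))
})

test_that("droplet detection requires calibration and handles blank input", {
  expect_error(detect_droplets(matrix(0, 64, 64), NULL,
                               segmentation_params()),
               "calibration")
  det <- detect_droplets(matrix(0, 64, 64), NULL, segmentation_params(),
                         pixel_size_um = 0.133)
  expect_equal(nrow(det$table), 0L)
})

test_that("a single planted spot is recovered with its half-maximum area", {
  set.seed(22)
  img <- matrix(0, 96, 96)
  # gaussian spot sigma 2 px; half-maximum disc radius = sigma*sqrt(2 ln 2)
  gr <- expand.grid(row = 1:96, col = 1:96)
  img <- img + matrix(exp(-((gr$row - 48)^2 + (gr$col - 51)^2) / (2 * 4)),
                      96, 96)
  det <- detect_droplets(noisy(img, 8), NULL, segmentation_params(),
                         pixel_size_um = 0.133)
  expect_equal(nrow(det$table), 1L)
  r_half <- 2 * sqrt(2 * log(2))
  want_area <- pi * r_half^2 * 0.133^2
  expect_lt(abs(det$table$area_um2[1] - want_area) / want_area, 0.2)
  expect_lt(abs(det$table$centroid_row[1] - 48), 1.5)
  expect_lt(abs(det$table$centroid_col[1] - 51), 1.5)
})

test_that("small and large droplets are both recovered at high recall", {
  sp <- field_spec(width_px = 420, height_px = 420, n_cells = 1,
                   ld_count_per_cell = list(mean = 55),
                   ld_area_um2_distribution = list(meanlog = log(0.15),
                                                   sdlog = 0.8,
                                                   min_um2 = 0.07,
                                                   max_um2 = 4),
                   snr = 8, seed = 41)
  fg <- generate_field(sp)
  tr <- fg$truth
  det <- detect_droplets(fg$image$channels$ld, tr$cell_masks,
                         segmentation_params(), sp$pixel_size_um)
  det <- merge_fragmented(det, fg$image$channels$ld, segmentation_params(),
                          tr$cell_masks)
  m <- match_detections(det, tr$ld_masks, nrow(tr$ld_table))
  small_gt <- which(tr$ld_table$area_um2 < 0.5)
  large_gt <- which(tr$ld_table$area_um2 >= 0.5)
  expect_gte(mean(m$matched_g[small_gt] > 0), 0.85)
  expect_gte(mean(m$matched_g[large_gt] > 0), 0.9)
})

test_that("detection is translation-equivariant away from borders", {
  set.seed(23)
  img <- matrix(0, 128, 128)
  for (ctr in list(c(40, 40), c(60, 80), c(90, 55)))
    img <- paint_disc(img, ctr[1], ctr[2], 2.5)
  img <- EBImage::gblur(img, 0.8)
  dr <- 7L; dc <- 5L
  shifted <- matrix(0, 128, 128)
  shifted[(1 + dr):128, (1 + dc):128] <- img[1:(128 - dr), 1:(128 - dc)]
  d1 <- detect_droplets(img, NULL, segmentation_params(), 0.133)
  d2 <- detect_droplets(shifted, NULL, segmentation_params(), 0.133)
  expect_equal(nrow(d2$table), nrow(d1$table))
  o1 <- order(d1$table$centroid_row, d1$table$centroid_col)
  o2 <- order(d2$table$centroid_row, d2$table$centroid_col)
  expect_equal(d2$table$centroid_row[o2], d1$table$centroid_row[o1] + dr,
               tolerance = 1e-8)
  expect_equal(d2$table$centroid_col[o2], d1$table$centroid_col[o1] + dc,
               tolerance = 1e-8)
})

test_that("fragment merging repairs split droplets and respects valleys", {
  params <- segmentation_params()
  # one large disc, artificially split into two abutting half masks
  img <- matrix(0, 64, 64)
  img <- paint_disc(img, 32, 32, 6)
  img <- EBImage::gblur(img, 0.8)
  full <- lipodrop:::.disc_pixels(32, 32, 6, 64, 64)
  left <- full[full[, 2] <= 31, , drop = FALSE]
  right <- full[full[, 2] >= 33, , drop = FALSE]   # one-column gap
  labels <- matrix(0L, 64, 64)
  labels[left] <- 1L; labels[right] <- 2L
  frag <- droplet_records(labels, img, 0.133)
  merged <- merge_fragmented(frag, img, params)
  expect_equal(nrow(merged$table), 1L)
  expect_lt(abs(merged$table$area_um2[1] - nrow(full) * 0.133^2) /
              (nrow(full) * 0.133^2), 0.2)

  # two distinct droplets separated by a deep valley stay separate
  img2 <- matrix(0, 64, 64)
  img2 <- paint_disc(img2, 32, 24, 4)
  img2 <- paint_disc(img2, 32, 38, 4)
  img2 <- EBImage::gblur(img2, 0.8)
  lab2 <- matrix(0L, 64, 64)
  lab2[lipodrop:::.disc_pixels(32, 24, 4, 64, 64)] <- 1L
  lab2[lipodrop:::.disc_pixels(32, 38, 4, 64, 64)] <- 2L
  two <- droplet_records(lab2, img2, 0.133)
  kept <- merge_fragmented(two, img2, params)
  expect_equal(nrow(kept$table), 2L)

  # single detection is a fixed point
  one <- droplet_records(matrix(as.integer(paint_disc(matrix(0, 30, 30),
                                                      15, 15, 3)), 30, 30),
                         img[1:30, 1:30], 0.133)
  expect_equal(nrow(merge_fragmented(one, img[1:30, 1:30], params)$table), 1L)
})

test_that("merging never decreases area nor increases droplet count", {
  set.seed(24)
  for (rep in 1:5) {
    cfgr <- random_droplet_config(12, dim = 72)
    img <- matrix(0, 72, 72)
    img[cfgr$droplets$labels > 0L] <- 1
    img <- EBImage::gblur(img, 0.8)
    before <- cfgr$droplets
    after <- merge_fragmented(before, img, segmentation_params())
    expect_lte(nrow(after$table), nrow(before$table))
    expect_gte(min(after$table$area_um2), min(before$table$area_um2))
    expect_equal(sum(after$table$area_um2), sum(before$table$area_um2),
                 tolerance = 1e-12)
  }
})

test_that("droplet records satisfy their geometric invariants", {
  set.seed(25)
  cfgr <- random_droplet_config(8, dim = 60)
  tab <- cfgr$droplets$table
  for (k in seq_len(nrow(tab))) {
    npx <- nrow(cfgr$droplets$px[[k]])
    expect_equal(tab$area_um2[k], npx * 0.133^2)
    expect_equal(tab$equivalent_diameter_um[k],
                 2 * sqrt(tab$area_um2[k] / pi))
    # boundary pixels are a subset of the mask
    key <- function(p) p[, 1] * 1e4 + p[, 2]
    expect_true(all(key(cfgr$droplets$boundary[[k]]) %in%
                      key(cfgr$droplets$px[[k]])))
  }
})
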