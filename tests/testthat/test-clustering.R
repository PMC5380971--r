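test_that("boundary gap follows pixel-centre geometry", {
  a <- cbind(5, 5)
  expect_equal(boundary_gap(a, a), 0)                    # identical masks
  expect_equal(boundary_gap(a, cbind(6, 5)), 1)          # 4-adjacent
  expect_equal(boundary_gap(a, cbind(8, 9)), 5)          # offset (3, 4)
  expect_error(boundary_gap(a, a[0, , drop = FALSE]), "empty")
})

test_that("the 2 px threshold at 0.133 um/px is the 0.266 um criterion", {
  expect_equal(2 * 0.133, 0.266)
  # a pair at exactly 2 px gap is clustered at the default threshold
  labels <- matrix(0L, 20, 20)
  labels[10, 5:7] <- 1L
  labels[10, 10:12] <- 2L      # nearest centres (10,7) and (10,10): 3 px
  labels[10, 9:11] <- 2L       # move to gap 2
  dr <- droplet_records(labels, NULL, 0.133, matrix(1L, 20, 20))
  fc <- find_clusters(dr, threshold_px = 0.266 / 0.133)
  expect_equal(nrow(fc$clusters), 1L)
})

test_that("cluster linkage is the transitive closure of the gap relation", {
  # chain A-B = 2, B-C = 2, A-C > threshold: one cluster of three
  labels <- matrix(0L, 30, 40)
  labels[15, 5:8] <- 1L
  labels[15, 10:13] <- 2L
  labels[15, 15:18] <- 3L
  dr <- droplet_records(labels, NULL, 0.133, matrix(1L, 30, 40))
  fc <- find_clusters(dr, 2)
  expect_equal(nrow(fc$clusters), 1L)
  expect_equal(fc$clusters$n_lds, 3L)
  expect_equal(fc$clusters$member_ids, "1;2;3")

  # all gaps above threshold: only singletons
  labels2 <- matrix(0L, 30, 40)
  labels2[10, 5] <- 1L; labels2[10, 15] <- 2L; labels2[25, 30] <- 3L
  dr2 <- droplet_records(labels2, NULL, 0.133, matrix(1L, 30, 40))
  fc2 <- find_clusters(dr2, 2)
  expect_equal(nrow(fc2$clusters), 0L)
  expect_true(all(fc2$membership == 0L))

  # empty input
  fc0 <- find_clusters(droplet_records(matrix(0L, 5, 5), NULL, 0.133), 2)
  expect_equal(nrow(fc0$clusters), 0L)
})

test_that("clusters match the brute-force oracle on random configurations", {
  set.seed(31)
  for (rep in 1:40) {
    n <- sample(3:15, 1)
    cfgr <- random_droplet_config(n, dim = 56)
    fc <- find_clusters(cfgr$droplets, 2)
    got <- lapply(seq_len(max(c(0L, fc$membership))), function(k)
      sort(as.integer(names(fc$membership)[fc$membership == k])))
    want <- oracle_clusters(cfgr$px, 2)
    expect_identical(partition_key(got), partition_key(want))
    # partition property: clustered + singletons = total
    expect_equal(sum(fc$membership > 0L) + sum(fc$membership == 0L),
                 nrow(cfgr$droplets$table))
  }
})

test_that("raising the threshold only coarsens the partition", {
  set.seed(32)
  for (rep in 1:8) {
    cfgr <- random_droplet_config(12, dim = 56)
    f1 <- find_clusters(cfgr$droplets, 2)
    f2 <- find_clusters(cfgr$droplets, 4)
    # number of components (clusters + singletons) never increases
    n1 <- nrow(f1$clusters) + sum(f1$membership == 0L)
    n2 <- nrow(f2$clusters) + sum(f2$membership == 0L)
    expect_lte(n2, n1)
    # every cluster at the small threshold stays together at the large one
    for (k in seq_len(max(c(0L, f1$membership)))) {
      ids <- names(f1$membership)[f1$membership == k]
      expect_equal(length(unique(f2$membership[ids])), 1L)
    }
  }
})

test_that("cluster statistics match closed forms and a two-pass oracle", {
  expect_equal(unname(cluster_size_stats(c(1, 1))), c(1, 0))
  st <- cluster_size_stats(c(0.5, 1.5))
  expect_equal(unname(st[1]), 1)
  expect_equal(unname(st[2]), sqrt(2 * 0.25), tolerance = 1e-12)
  expect_error(cluster_size_stats(1), ">= 2")

  set.seed(33)
  a <- rlnorm(1000, log(0.2), 0.7)
  st2 <- cluster_size_stats(a)
  m <- sum(a) / length(a)
  s2 <- sum((a - m)^2) / (length(a) - 1)
  expect_equal(unname(st2[1]), m, tolerance = 1e-14)
  expect_equal(unname(st2[2]), sqrt(s2), tolerance = 1e-14)
  # population-divisor option
  stn <- cluster_size_stats(a, sd_divisor = "n")
  expect_equal(unname(stn[2]), sqrt(s2 * (length(a) - 1) / length(a)),
               tolerance = 1e-12)
})

test_that("cluster rates per 100 LDs are exhaustive and bounded", {
  r <- clusters_per_100_lds(10, c(2, 3))
  expect_equal(unname(r[c("rate_2", "rate_3")]), c(10, 10))
  expect_equal(unname(r["rate_6plus"]), 0)
  expect_equal(unname(clusters_per_100_lds(5, integer(0))), rep(0, 5))
  expect_true(all(is.na(clusters_per_100_lds(0, integer(0)))))
  expect_error(clusters_per_100_lds(10, 1), ">= 2")

  # counting oracle: sum_k k * rate_k / 100 = clustered fraction <= 1
  set.seed(34)
  for (rep in 1:25) {
    n <- sample(6:40, 1)
    sizes <- integer(0)
    left <- n
    while (left >= 2 && runif(1) < 0.7) {
      s <- if (left <= 2) 2L else sample(seq(2L, min(6L, left)), 1)
      sizes <- c(sizes, s)
      left <- left - s
    }
    r <- clusters_per_100_lds(n, sizes)
    ks <- c(2, 3, 4, 5, 6)
    # the 6plus bucket pools all larger clusters; reconstruct exactly
    frac <- (sum(ks[1:4] * r[1:4]) + sum(sizes[sizes >= 6]) / n * 100) / 100
    expect_equal(frac, sum(sizes) / n, tolerance = 1e-12)
    expect_lte(frac, 1 + 1e-12)
  }
})

test_that("the size histogram uses left-closed right-open bins", {
  h <- size_histogram(c(0.3, 0.7, 1.7))
  expect_equal(unname(h$counts), c(1, 1, 0, 1, 0))
  expect_equal(unname(size_histogram(0.5)$counts), c(0, 1, 0, 0, 0))
  expect_equal(sum(size_histogram(numeric(0))$counts), 0)
  expect_error(size_histogram(1, bin_edges_um2 = c(0, 1, 1)),
               "strictly increasing")
})
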