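# Shared fixtures and independent oracles used across the test files.

# a small, quick field for pipeline-level tests
small_field_spec <- function(seed, snr = 10, ...) {
  field_spec(width_px = 420, height_px = 420, n_cells = 1,
             ld_count_per_cell = list(mean = 60), cluster_fraction = 0.15,
             seed = seed, snr = snr, ...)
}

# paint a disc of value `amp` into a matrix (used to build tiny planted
# images without the full generator)
paint_disc <- function(img, row, col, r, amp = 1) {
  px <- lipodrop:::.disc_pixels(row, col, r, nrow(img), ncol(img))
  img[px] <- amp
  img
}

# brute-force pairwise-gap oracle: O(n^2) over full masks, then
# transitive closure via repeated boolean matrix products -- independent
# of the package's graph-based implementation
oracle_clusters <- function(px_list, threshold) {
  n <- length(px_list)
  adj <- diag(TRUE, n)
  if (n >= 2)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      a <- px_list[[i]]; b <- px_list[[j]]
      d2min <- Inf
      for (k in seq_len(nrow(a)))
        d2min <- min(d2min, min((b[, 1] - a[k, 1])^2 + (b[, 2] - a[k, 2])^2))
      adj[i, j] <- adj[j, i] <- sqrt(d2min) <= threshold
    }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comp <- rep(0L, n)
  cid <- 0L
  for (i in seq_len(n)) if (comp[i] == 0L) {
    cid <- cid + 1L
    comp[adj[i, ]] <- cid
  }
  # return only components of size >= 2, as sorted member-id sets
  sets <- split(seq_len(n), comp)
  sets <- sets[lengths(sets) >= 2]
  unname(lapply(sets, sort))
}

# canonical string form of a cluster partition for set comparison
partition_key <- function(sets) {
  sort(vapply(sets, function(s) paste(sort(s), collapse = ","), ""))
}

# random droplet configuration on a small grid: n discs with radii 1-3,
# returns an ld_droplets object plus the raw pixel sets
random_droplet_config <- function(n, dim = 64, one_cell = TRUE) {
  labels <- matrix(0L, dim, dim)
  px <- list()
  k <- 0L
  guard <- 0L
  while (k < n && guard < 500L) {
    guard <- guard + 1L
    r <- runif(1, 1, 3)
    p <- lipodrop:::.disc_pixels(runif(1, r + 2, dim - r - 2),
                                 runif(1, r + 2, dim - r - 2), r, dim, dim)
    if (is.null(p) || nrow(p) == 0 || any(labels[p] > 0L)) next
    k <- k + 1L
    labels[p] <- k
    px[[k]] <- p
  }
  cells <- if (one_cell) matrix(1L, dim, dim) else NULL
  list(droplets = droplet_records(labels, NULL, 0.133, cells), px = px)
}

# one-to-one overlap matching of detections against a ground-truth label
# map; returns precision, recall, F1 and the matched index pairs
match_detections <- function(det, gt_labels, gt_n) {
  nD <- nrow(det$table)
  ov <- matrix(0, nD, gt_n)
  for (i in seq_len(nD)) {
    g <- gt_labels[det$px[[i]]]
    tb <- table(g[g > 0])
    for (nm in names(tb)) ov[i, as.integer(nm)] <- tb[[nm]]
  }
  matched_d <- rep(0L, nD); matched_g <- rep(0L, gt_n)
  for (o in order(-ov)) {
    if (ov[o] <= 0) break
    i <- (o - 1) %% nD + 1; j <- (o - 1) %/% nD + 1
    if (matched_d[i] == 0 && matched_g[j] == 0) {
      matched_d[i] <- j; matched_g[j] <- i
    }
  }
  tp <- sum(matched_d > 0)
  prec <- if (nD) tp / nD else NA_real_
  rec <- tp / gt_n
  list(precision = prec, recall = rec,
       f1 = 2 * prec * rec / (prec + rec),
       matched_d = matched_d, matched_g = matched_g)
}
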