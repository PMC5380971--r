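# Internal pixel-geometry helpers shared across modules.

# 8-connected labeling: bwlabel is 4-connected, so merge labels that touch
# diagonally through an igraph components pass
.label8 <- function(mask) {
  l4 <- EBImage::bwlabel(mask > 0)
  mx <- max(l4)
  if (mx <= 1) return(matrix(as.integer(l4), nrow(l4), ncol(l4)))
  nr <- nrow(l4); nc <- ncol(l4)
  p1 <- rbind(cbind(as.integer(l4[-nr, -nc]), as.integer(l4[-1, -1])),
              cbind(as.integer(l4[-nr, -1]), as.integer(l4[-1, -nc])))
  p1 <- p1[p1[, 1] > 0L & p1[, 2] > 0L & p1[, 1] != p1[, 2], , drop = FALSE]
  if (nrow(p1) == 0) return(matrix(as.integer(l4), nr, nc))
  g <- igraph::graph_from_edgelist(matrix(as.character(p1), ncol = 2),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, sum(!as.character(seq_len(mx)) %in%
                                     igraph::V(g)$name),
                            name = setdiff(as.character(seq_len(mx)),
                                           igraph::V(g)$name))
  comp <- igraph::components(g)$membership
  remap <- integer(mx)
  remap[as.integer(names(comp))] <- as.integer(comp)
  out <- matrix(0L, nr, nc)
  nz <- l4 > 0
  out[nz] <- remap[as.integer(l4[nz])]
  # renumber compactly and deterministically (by first pixel occurrence)
  u <- unique(out[out > 0L])
  out[out > 0L] <- match(out[out > 0L], u)
  out
}

# boundary pixels of every labelled object: pixels whose 4-neighbourhood
# leaves the object (or the image)
.boundary_mask <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  pad <- matrix(-1L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- labels
  ctr <- pad[2:(nr + 1L), 2:(nc + 1L)]
  up    <- pad[1:nr, 2:(nc + 1L)]
  down  <- pad[3:(nr + 2L), 2:(nc + 1L)]
  left  <- pad[2:(nr + 1L), 1:nc]
  right <- pad[2:(nr + 1L), 3:(nc + 2L)]
  (ctr > 0L) & (up != ctr | down != ctr | left != ctr | right != ctr)
}

# bilinear interpolation of image values at fractional (row, col) positions;
# positions are clamped to the image domain
.bilinear_sample <- function(image, rows, cols) {
  nr <- nrow(image); nc <- ncol(image)
  rows <- pmin(pmax(rows, 1), nr)
  cols <- pmin(pmax(cols, 1), nc)
  r0 <- pmin(floor(rows), nr - 1L); c0 <- pmin(floor(cols), nc - 1L)
  if (nr == 1) r0 <- rep(1, length(rows))
  if (nc == 1) c0 <- rep(1, length(cols))
  fr <- rows - r0; fc <- cols - c0
  i00 <- image[cbind(r0, c0)]
  i10 <- image[cbind(pmin(r0 + 1, nr), c0)]
  i01 <- image[cbind(r0, pmin(c0 + 1, nc))]
  i11 <- image[cbind(pmin(r0 + 1, nr), pmin(c0 + 1, nc))]
  i00 * (1 - fr) * (1 - fc) + i10 * fr * (1 - fc) +
    i01 * (1 - fr) * fc + i11 * fr * fc
}

# pixel mask of a disc: pixel centres within radius r of (cr, cc);
# optional axis ratio q renders a slight ellipse with orientation theta
.disc_pixels <- function(cr, cc, r, nr, nc, q = 1, theta = 0) {
  rr <- seq(max(1L, floor(cr - r - 2)), min(nr, ceiling(cr + r + 2)))
  cc2 <- seq(max(1L, floor(cc - r - 2)), min(nc, ceiling(cc + r + 2)))
  if (length(rr) == 0 || length(cc2) == 0) return(NULL)
  gr <- expand.grid(row = rr, col = cc2)
  dx <- gr$row - cr; dy <- gr$col - cc
  if (q != 1) {
    u <- dx * cos(theta) + dy * sin(theta)
    v <- -dx * sin(theta) + dy * cos(theta)
    keep <- (u / (r * q))^2 + (v * q / r)^2 <= 1
  } else {
    keep <- dx * dx + dy * dy <= r * r
  }
  as.matrix(gr[keep, , drop = FALSE])
}

# minimum distance between two pixel-coordinate sets (n x 2 matrices)
.min_cross_dist <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) stop("empty pixel set")
  best <- Inf
  for (i in seq_len(nrow(a))) {
    d2 <- (b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2
    m <- min(d2)
    if (m < best) best <- m
    if (best == 0) break
  }
  sqrt(best)
}

# 2D local maxima (>= against all 8 neighbours) strictly above a
# threshold; returns n x 2 (row, col)
.local_maxima <- function(image, threshold) {
  nr <- nrow(image); nc <- ncol(image)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- image
  ctr <- image
  ok <- ctr > threshold
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
    ok <- ok & (ctr >= nb)
  }
  which(ok, arr.ind = TRUE)
}
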