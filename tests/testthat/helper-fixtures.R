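# Shared fixtures and independent oracles for the test suite.

# small desk-scale geometry used throughout
test_geometry <- function(nx = 160, ny = 160, nz = 32, dx = 0.5, dz = 1) {
  acquisition_geometry(nx = nx, ny = ny, nz = nz, dx = dx, dz = dz)
}

# digitized disk mask (pixel-centre-inside rule), radius in px
disk_mask <- function(r, pad = 6) {
  n <- 2 * (r + pad) + 1
  c0 <- r + pad + 1
  yy <- matrix(rep(seq_len(n), n), n)
  xx <- t(yy)
  (yy - c0)^2 + (xx - c0)^2 <= r^2
}

# digitized axis-aligned ellipse mask, semi-axes (a_x, b_y) in px
ellipse_mask <- function(a, b, pad = 4) {
  nxp <- 2 * (a + pad) + 1
  nyp <- 2 * (b + pad) + 1
  cx <- a + pad + 1
  cy <- b + pad + 1
  yy <- matrix(rep(seq_len(nyp), nxp), nyp)
  xx <- matrix(rep(seq_len(nxp), each = nyp), nyp)
  ((xx - cx) / a)^2 + ((yy - cy) / b)^2 <= 1
}

# random connected blob: union of random disks around a centre
random_blob <- function(seed, n = 80, spread = 18, rmax = 6) {
  set.seed(seed)
  m <- matrix(FALSE, 2 * spread + 2 * rmax + 6, 2 * spread + 2 * rmax + 6)
  c0 <- (nrow(m) + 1) / 2
  px <- c0; py <- c0
  for (i in seq_len(n)) {
    ang <- runif(1, 0, 2 * pi)
    px <- min(max(px + cos(ang) * runif(1, 0, 4), rmax + 2), nrow(m) - rmax - 2)
    py <- min(max(py + sin(ang) * runif(1, 0, 4), rmax + 2), nrow(m) - rmax - 2)
    r <- runif(1, 1, rmax)
    yy <- matrix(rep(seq_len(nrow(m)), ncol(m)), nrow(m))
    xx <- t(yy)
    m <- m | ((yy - py)^2 + (xx - px)^2 <= r^2)
  }
  m
}

# brute-force convex hull area/perimeter of 2D points via grDevices::chull is
# not independent enough; use an O(n^2) gift-wrapping oracle instead
hull2d_oracle <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  start <- which.min(pts[, 1] + 1e-9 * pts[, 2])
  hull <- start
  repeat {
    p <- hull[length(hull)]
    cand <- setdiff(seq_len(n), p)
    q <- cand[1]
    for (r in cand[-1]) {
      cr <- (pts[q, 1] - pts[p, 1]) * (pts[r, 2] - pts[p, 2]) -
        (pts[q, 2] - pts[p, 2]) * (pts[r, 1] - pts[p, 1])
      d_q <- sum((pts[q, ] - pts[p, ])^2)
      d_r <- sum((pts[r, ] - pts[p, ])^2)
      if (cr < 0 || (abs(cr) < 1e-12 && d_r > d_q)) q <- r
    }
    if (q == start) break
    hull <- c(hull, q)
    if (length(hull) > n) stop("gift wrapping failed")
  }
  hp <- pts[hull, , drop = FALSE]
  x <- hp[, 1]; y <- hp[, 2]
  area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  per <- sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
  list(area = area, perimeter = per)
}

# Brute-force 3D hull by exhaustive half-space enumeration: every plane
# through three points with ALL points on one side is a supporting plane;
# faces are the deduplicated supporting planes, each contributing a pyramid
# (face area x distance to the interior centroid / 3). Handles coplanar
# voxel-corner faces exactly. Vectorized over triples; fine up to ~150 pts.
hull3d_oracle <- function(pts, chunk = 20000) {
  pts <- unique(pts)
  n <- nrow(pts)
  stopifnot(n >= 4)
  eps <- 1e-9 * max(abs(pts), 1)
  tri <- t(utils::combn(n, 3))
  p1 <- pts[tri[, 1], , drop = FALSE]
  u <- pts[tri[, 2], , drop = FALSE] - p1
  v <- pts[tri[, 3], , drop = FALSE] - p1
  nrm <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
               u[, 3] * v[, 1] - u[, 1] * v[, 3],
               u[, 1] * v[, 2] - u[, 2] * v[, 1])
  len <- sqrt(rowSums(nrm^2))
  ok <- len > eps
  nrm <- nrm[ok, , drop = FALSE] / len[ok]
  off <- rowSums(nrm * p1[ok, , drop = FALSE])
  keep <- logical(nrow(nrm))
  for (s in seq(1, nrow(nrm), by = chunk)) {
    e <- min(s + chunk - 1, nrow(nrm))
    D <- nrm[s:e, , drop = FALSE] %*% t(pts) - off[s:e]
    keep[s:e] <- (matrixStats_rowMaxs(D) <= eps) |
      (matrixStats_rowMins(D) >= -eps)
  }
  nrm <- nrm[keep, , drop = FALSE]; off <- off[keep]
  ctr <- colMeans(pts)
  flip <- as.numeric(nrm %*% ctr) - off > 0
  nrm[flip, ] <- -nrm[flip, ]
  off[flip] <- -off[flip]
  key <- paste(round(nrm[, 1], 7), round(nrm[, 2], 7),
               round(nrm[, 3], 7), round(off, 6))
  uq <- !duplicated(key)
  nrm <- nrm[uq, , drop = FALSE]; off <- off[uq]
  vol <- 0; area <- 0
  for (f in seq_len(nrow(nrm))) {
    d <- as.numeric(pts %*% nrm[f, ]) - off[f]
    on <- which(abs(d) <= eps)
    if (length(on) < 3) next
    nv <- nrm[f, ]
    a1 <- if (abs(nv[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- a1 - sum(a1 * nv) * nv
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(nv[2] * e1[3] - nv[3] * e1[2],
            nv[3] * e1[1] - nv[1] * e1[3],
            nv[1] * e1[2] - nv[2] * e1[1])
    q <- cbind(pts[on, , drop = FALSE] %*% e1, pts[on, , drop = FALSE] %*% e2)
    h <- grDevices::chull(q)
    x <- q[h, 1]; y <- q[h, 2]
    A <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
    area <- area + A
    vol <- vol + A * abs(off[f] - sum(nrm[f, ] * ctr)) / 3
  }
  list(volume = vol, area = area)
}

matrixStats_rowMaxs <- function(m) apply(m, 1, max)
matrixStats_rowMins <- function(m) apply(m, 1, min)

# hull vertices can only be corners extremal along some lattice line; this
# lossless reduction keeps the oracle tractable on voxel-corner clouds
reduce_corner_cloud <- function(pts) {
  pts <- unique(pts)
  keep <- rep(FALSE, nrow(pts))
  for (ax in 1:3) {
    others <- setdiff(1:3, ax)
    key <- paste(pts[, others[1]], pts[, others[2]])
    for (k in unique(key)) {
      rows <- which(key == k)
      keep[rows[which.min(pts[rows, ax])]] <- TRUE
      keep[rows[which.max(pts[rows, ax])]] <- TRUE
    }
  }
  pts[keep, , drop = FALSE]
}

# exhaustive 256-bin Otsu: plain loop over all split points
otsu_oracle <- function(v, n_bins = 256) {
  rng <- range(v)
  h <- graphics::hist(v, breaks = seq(rng[1], rng[2], length.out = n_bins + 1),
                      plot = FALSE)
  best <- -Inf; best_t <- NA
  for (t in 1:(n_bins - 1)) {
    w1 <- sum(h$counts[1:t]); w2 <- sum(h$counts[(t + 1):n_bins])
    if (w1 == 0 || w2 == 0) next
    m1 <- sum(h$counts[1:t] * h$mids[1:t]) / w1
    m2 <- sum(h$counts[(t + 1):n_bins] * h$mids[(t + 1):n_bins]) / w2
    s <- w1 * w2 * (m1 - m2)^2
    if (s > best) { best <- s; best_t <- t }
  }
  h$mids[best_t]
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
mw_enum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  u_stat <- function(x, y) {
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_stat(a, b)
  m <- length(b)
  u_center <- n * m / 2
  combs <- utils::combn(length(pooled), n)
  us <- apply(combs, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  mean(abs(us - u_center) >= abs(u_obs - u_center) - 1e-9)
}

# tiny rendered scene shared by several tests (cheap: 128x128x28 voxels,
# i.e. a 64 x 64 x 28 um field that hosts ~10 cells at default spacing)
small_scene <- function(seed = 11, n_cells = 8, ...) {
  g <- test_geometry(nx = 128, ny = 128, nz = 28)
  generate_scene(scene_params(geometry = g, n_cells = n_cells,
                              n_vessels = 1L, ...), seed = seed)
}
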