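sp1 <- c(y = 1, x = 1, z = 1)

ball_array <- function(centers, r, nx = 40, ny = 40, nz = 40, dx = 1) {
  g <- acquisition_geometry(nx = nx, ny = ny, nz = nz, dx = dx, dz = dx)
  rasterize_balls(g, centers, r)
}

test_that("probability smoothing: identity, constants, mass conservation", {
  set.seed(51)
  f <- array(runif(10 * 10 * 6), c(10, 10, 6))
  expect_identical(smooth_probability(f, 0), f)
  cst <- array(0.4, c(8, 8, 4))
  expect_lt(max(abs(smooth_probability(cst, 1) - 0.4)), 1e-12)
  # single voxel of mass 1: reflect boundary conserves total mass
  imp <- array(0, c(15, 15, 15))
  imp[8, 8, 8] <- 1
  expect_lt(abs(sum(smooth_probability(imp, 1)) - 1), 1e-3)
  expect_error(smooth_probability(f, -1), "sigma")
  sm <- smooth_probability(f, 1.5)
  expect_true(all(sm >= 0 & sm <= 1))
})

test_that("Otsu threshold separates a bimodal field and rejects constants", {
  v <- c(rep(0.1, 500), rep(0.9, 500))
  ot <- otsu_threshold(array(v, c(10, 10, 10)))
  expect_gt(ot$threshold, 0.1)
  expect_lt(ot$threshold, 0.9)
  expect_equal(sum(ot$mask), 500)
  expect_error(otsu_threshold(array(1, c(4, 4, 4))), "constant")
})

test_that("Otsu equals exhaustive 256-bin search and is shift-equivariant", {
  set.seed(52)
  for (rep in 1:20) {
    v <- switch(rep %% 4 + 1,
      c(rnorm(400, 0.2, 0.05), rnorm(300, 0.8, 0.1)),
      runif(600),
      c(rexp(500, 5), rnorm(200, 1, 0.2)),
      rbeta(700, 2, 5))
    ot <- otsu_threshold(v)
    expect_equal(ot$threshold, otsu_oracle(v), tolerance = 1e-12)
    # adding a constant shifts the threshold but not the mask
    ot2 <- otsu_threshold(v + 3)
    expect_equal(as.logical(ot2$mask), as.logical(ot$mask))
  }
})

test_that("vasculature exclusion removes only high-probability vessel voxels", {
  mask <- array(TRUE, c(6, 6, 3))
  pv <- array(0, c(6, 6, 3, 3), dimnames = list(NULL, NULL, NULL,
    c("microglia", "vasculature", "background")))
  pmap0 <- structure(pv, class = "probability_map")
  expect_equal(as.logical(exclude_vasculature(mask, pmap0, 0.5)),
               as.logical(mask))

  pv[2, 3, 1, "vasculature"] <- 0.9
  pv[5, 5, 2, "vasculature"] <- 0.5
  pv[1, 1, 1, "vasculature"] <- 0.49
  pmap <- structure(pv, class = "probability_map")
  out <- exclude_vasculature(mask, pmap, 0.5)
  expect_false(out[2, 3, 1])
  expect_false(out[5, 5, 2])  # boundary: >= threshold removed
  expect_true(out[1, 1, 1])
  expect_true(all(!out | mask))  # subset property

  # v_threshold = 1 with no voxel at exactly 1: mask unchanged
  expect_equal(as.logical(exclude_vasculature(mask, pmap, 1.0)),
               as.logical(mask))
  expect_error(exclude_vasculature(mask, pmap, 0), "v_threshold")
})

test_that("watershed separates disjoint and touching spheres", {
  # disjoint spheres: exactly the connected components
  m <- ball_array(rbind(c(12, 12, 20), c(12, 28, 20)), 6)
  labs <- separate_instances(m, sp1)
  expect_equal(n_labels(labs), 2L)
  cc <- array(microglia3d:::cpp_label3(as.logical(m), 40, 40, 40, 26L),
              dim(m))
  expect_true(all((labs > 0) == m))
  expect_equal(table(labs[labs > 0]), table(cc[cc > 0]),
               ignore_attr = TRUE)

  # overlapping spheres (r = 8, centres 12 apart): two labels, centroids
  # within 2 voxels of the true centres
  m2 <- ball_array(rbind(c(20, 14, 20), c(20, 26, 20)), 8)
  labs2 <- separate_instances(m2, sp1)
  expect_equal(n_labels(labs2), 2L)
  cents <- lapply(1:2, function(k) {
    colMeans(which(labs2 == k, arr.ind = TRUE))
  })
  truth <- list(c(20, 14, 20), c(20, 26, 20))
  err <- sapply(cents, function(cc) {
    min(sapply(truth, function(tt) sqrt(sum((cc - tt)^2))))
  })
  expect_true(all(err < 2))

  # a single convex solid is never split
  m3 <- ball_array(cbind(20, 20, 20), 9)
  labs3 <- separate_instances(m3, sp1)
  expect_equal(n_labels(labs3), 1L)
  expect_equal(as.logical(labs3 > 0), as.logical(m3))
})

test_that("watershed output partitions the mask exactly", {
  sc <- small_scene(seed = 53)
  mask <- sc$labels > 0L
  labs <- separate_instances(mask, attr(sc$labels, "spacing"))
  expect_equal(sum(label_sizes(labs)), sum(mask))
  expect_true(all((labs > 0L) == mask))
  # empty mask: empty labels, not an error
  e <- separate_instances(array(FALSE, c(5, 5, 5)), sp1)
  expect_equal(n_labels(e), 0L)
})

test_that("size filter thresholds volumes and reports rejections", {
  # three objects of volume 50, 150, 2000 um^3 at 1 um^3 voxels
  labs <- array(0L, c(30, 30, 20))
  labs[1:5, 1:5, 1:2] <- 1L          # 50
  labs[10:14, 10:15, 1:5] <- 2L      # 150
  labs[20:29, 20:29, 1:20] <- 3L     # 2000
  attr(labs, "spacing") <- sp1
  out <- size_filter(labs, 100)
  expect_equal(n_labels(out), 2L)
  rep_ <- attr(out, "size_filter_report")
  expect_equal(rep_$volume_um3, c(50, 150, 2000))
  expect_equal(rep_$kept, c(FALSE, TRUE, TRUE))
  # ids compacted: the 150-voxel object is now label 1
  expect_equal(sum(out == 1L), 150)

  expect_equal(as.integer(size_filter(labs, 0)), as.integer(labs))

  # monotonicity: raising the threshold never increases the count
  counts <- sapply(c(0, 60, 100, 200, 3000), function(mv) {
    n_labels(size_filter(labs, mv))
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("qc review applies decisions, compacts ids, validates labels", {
  labs <- array(0L, c(10, 10, 4))
  labs[1:3, 1:3, 1] <- 1L
  labs[5:7, 5:7, 2] <- 2L
  labs[8:9, 1:2, 3] <- 3L
  attr(labs, "spacing") <- sp1
  vox3 <- which(labs == 3L)

  expect_equal(as.integer(qc_review(labs)), as.integer(labs))
  none <- qc_review(labs, data.frame(label = 1:3, accept = TRUE))
  expect_equal(as.integer(none), as.integer(labs))
  all_out <- qc_review(labs, data.frame(label = 1:3, accept = FALSE))
  expect_equal(n_labels(all_out), 0L)

  drop2 <- qc_review(labs, data.frame(label = 2L, accept = FALSE))
  expect_equal(n_labels(drop2), 2L)
  # old label 3 renumbered to 2 with its voxel set preserved
  expect_equal(which(drop2 == 2L), vox3)
  expect_error(qc_review(labs, data.frame(label = 9L, accept = FALSE)),
               "nonexistent")
})
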