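sp1 <- c(y = 1, x = 1, z = 1)

cube_voxels <- function(n) {
  as.matrix(expand.grid(y = 1:n, x = 1:n, z = 1:n))
}

test_that("a solid cube has solidity exactly 1", {
  m3 <- metrics_3d(cube_voxels(10), sp1)
  expect_equal(m3$volume_um3, 1000)
  expect_equal(m3$hull_volume_um3, 1000, tolerance = 1e-12)
  expect_equal(m3$solidity_3d, 1)
  expect_false(m3$degenerate)
})

test_that("a digitized sphere is nearly solid, approaching 1 with resolution", {
  # under the corner-point hull convention the hull of a digitized ball is
  # inflated by about half a voxel in every direction, so solidity climbs
  # towards 1 as the pitch shrinks: ~0.84 at 1 um, ~0.91 at 0.5 um, ~0.95
  # at 0.25 um for an 8 um sphere
  sol <- vapply(c(1, 0.5, 0.25), function(h) {
    n <- ceiling(2 * (8 / h) + 8)
    g <- acquisition_geometry(nx = n, ny = n, nz = n, dx = h, dz = h)
    c0 <- n * h / 2
    ball <- rasterize_balls(g, cbind(c0, c0, c0), 8)
    metrics_3d(which(ball, arr.ind = TRUE), c(h, h, h))$solidity_3d
  }, numeric(1))
  expect_true(all(diff(sol) > 0))
  expect_gt(sol[1], 0.82)
  expect_gt(sol[2], 0.88)
  expect_gt(sol[3], 0.93)
  expect_true(all(sol <= 1))
})

test_that("hull volume and area match the exhaustive half-space oracle", {
  # plus-sign solid: two orthogonal 3 x 3 x 11 bars
  plus <- array(FALSE, c(15, 15, 7))
  plus[7:9, 3:13, 3:5] <- TRUE
  plus[3:13, 7:9, 3:5] <- TRUE
  vox <- which(plus, arr.ind = TRUE)
  m3 <- metrics_3d(vox, sp1)
  corners <- microglia3d:::voxel_corner_cloud(matrix(as.numeric(vox),
                                                    ncol = 3), sp1)
  oracle <- hull3d_oracle(reduce_corner_cloud(corners))
  expect_equal(m3$hull_volume_um3, oracle$volume, tolerance = 1e-9)
  expect_equal(m3$volume_um3 / oracle$volume, m3$solidity_3d,
               tolerance = 1e-9)

  # random small voxel blobs
  set.seed(61)
  for (rep in 1:3) {
    g <- acquisition_geometry(nx = 16, ny = 16, nz = 12, dx = 1, dz = 1)
    centers <- cbind(runif(2, 5, 11), runif(2, 5, 11), runif(2, 4, 8))
    blob <- rasterize_balls(g, centers, runif(2, 1.5, 2.3))
    vox <- which(blob, arr.ind = TRUE)
    m3 <- metrics_3d(vox, sp1)
    corners <- microglia3d:::voxel_corner_cloud(matrix(as.numeric(vox),
                                                      ncol = 3), sp1)
    oracle <- hull3d_oracle(reduce_corner_cloud(corners))
    expect_equal(m3$hull_volume_um3, oracle$volume, tolerance = 1e-9)
  }
})

test_that("z-projection is the any-hit collapse and is idempotent", {
  vox <- rbind(c(2, 3, 1), c(2, 3, 2), c(4, 5, 2))
  pr <- project_z(vox, c(6, 6))
  expect_true(pr[2, 3] && pr[4, 5])
  expect_equal(sum(pr), 2)
  # two identical slices stacked project to one slice
  a <- array(FALSE, c(5, 5, 2))
  a[2:3, 2:4, 1] <- TRUE
  a[2:3, 2:4, 2] <- TRUE
  expect_equal(project_z(a), a[, , 1])
  # a cylinder along z projects to the digitized disk
  dk <- disk_mask(10)
  cyl <- array(rep(dk, 8), c(dim(dk), 8))
  expect_equal(project_z(cyl), dk)
})

test_that("2D metrics of a square match the closed forms exactly", {
  sq <- matrix(FALSE, 14, 14)
  sq[3:12, 3:12] <- TRUE
  m2 <- metrics_2d(sq, 1)
  expect_equal(m2$area_um2, 100)
  expect_equal(m2$perimeter_um, 40)
  expect_equal(m2$hull_area_um2, 100, tolerance = 1e-12)
  expect_equal(m2$hull_perimeter_um, 40, tolerance = 1e-12)
  expect_equal(m2$solidity_2d, 1)
  expect_equal(m2$convexity, 1)
  expect_equal(m2$circularity, pi / 4, tolerance = 1e-12)
  expect_equal(m2$axis_ratio, 1, tolerance = 1e-12)
})

test_that("a large digitized disk approaches the analytic circle", {
  m2 <- metrics_2d(disk_mask(50), 1)
  expect_lt(abs(m2$circularity - 1), 0.08)
  expect_lt(abs(m2$axis_ratio - 1), 0.02)
  expect_lt(abs(m2$perimeter_um / (2 * pi * 50) - 1), 0.05)
})

test_that("a 4:1 digitized ellipse has axis ratio near 0.25", {
  m2 <- metrics_2d(ellipse_mask(80, 20), 1)
  expect_lt(abs(m2$axis_ratio - 0.25), 0.05 * 0.25)
})

test_that("2D hull quantities match the gift-wrapping oracle", {
  set.seed(62)
  for (rep in 1:5) {
    blob <- random_blob(seed = 100 + rep)
    m2 <- metrics_2d(blob, 1)
    idx <- which(blob, arr.ind = TRUE)
    corners <- unique(rbind(
      cbind(idx[, 1] - 0.5, idx[, 2] - 0.5),
      cbind(idx[, 1] - 0.5, idx[, 2] + 0.5),
      cbind(idx[, 1] + 0.5, idx[, 2] - 0.5),
      cbind(idx[, 1] + 0.5, idx[, 2] + 0.5)))
    oracle <- hull2d_oracle(corners)
    expect_equal(m2$hull_area_um2, oracle$area, tolerance = 1e-9)
    expect_equal(m2$hull_perimeter_um, oracle$perimeter, tolerance = 1e-9)
  }
})

test_that("shape ratios stay within (0, 1] on random blobs", {
  for (rep in 1:10) {
    blob <- random_blob(seed = 200 + rep)
    m2 <- metrics_2d(blob, 1)
    expect_gt(m2$solidity_2d, 0)
    expect_lte(m2$solidity_2d, 1)
    expect_gt(m2$convexity, 0)
    expect_lte(m2$convexity, 1)
    expect_gt(m2$circularity, 0)
    expect_lte(m2$circularity, 1 + 1e-9)
    expect_gt(m2$axis_ratio, 0)
    expect_lte(m2$axis_ratio, 1)
  }
})

test_that("degenerate single-voxel ROIs take the unit-cube conventions", {
  m3 <- metrics_3d(cbind(3, 3, 3), sp1)
  expect_equal(m3$solidity_3d, 1)
  m2 <- metrics_2d(project_z(cbind(3, 3, 3), c(5, 5)), 1)
  expect_equal(m2$circularity, pi / 4, tolerance = 1e-12)
  expect_equal(m2$axis_ratio, 1)
})

test_that("metrics scale correctly with voxel spacing", {
  set.seed(63)
  g <- acquisition_geometry(nx = 30, ny = 30, nz = 20, dx = 1, dz = 1)
  blob <- rasterize_balls(g, rbind(c(12, 12, 8), c(18, 16, 12)), c(5, 4))
  vox <- which(blob, arr.ind = TRUE)
  s <- 2.5
  m1 <- metrics_3d(vox, sp1)
  m2 <- metrics_3d(vox, s * sp1)
  expect_equal(m2$volume_um3, s^3 * m1$volume_um3)
  expect_equal(m2$hull_volume_um3, s^3 * m1$hull_volume_um3,
               tolerance = 1e-9)
  expect_equal(m2$solidity_3d, m1$solidity_3d, tolerance = 1e-9)

  pr <- project_z(vox, c(30, 30))
  a1 <- metrics_2d(pr, 1)
  a2 <- metrics_2d(pr, s)
  expect_equal(a2$area_um2, s^2 * a1$area_um2)
  expect_equal(a2$perimeter_um, s * a1$perimeter_um)
  for (ratio in c("solidity_2d", "convexity", "circularity", "axis_ratio")) {
    expect_equal(a2[[ratio]], a1[[ratio]], tolerance = 1e-12, info = ratio)
  }
})

test_that("amoeboid cells score higher solidity and circularity", {
  g <- test_geometry()
  amoeboid <- generate_scene(scene_params(
    geometry = g, n_cells = 12, amoeboid_range = c(0.95, 1)), seed = 71)
  ramified <- generate_scene(scene_params(
    geometry = g, n_cells = 12, amoeboid_range = c(0, 0.05)), seed = 71)
  ma <- measure_cells(amoeboid$labels)
  mr <- measure_cells(ramified$labels)
  expect_gt(mean(ma$solidity_3d), mean(mr$solidity_3d))
  expect_gt(mean(ma$circularity), mean(mr$circularity))
})

test_that("count densities follow both reporting conventions", {
  g <- acquisition_geometry(nx = 2048, ny = 2048, nz = 40)
  cd <- count_density(50, g)
  expect_equal(cd$density_3d_mm3, 50 / (0.31945^2 * 0.040), tolerance = 1e-6)
  expect_equal(cd$density_2d_mm2, 50 / 0.31945^2, tolerance = 1e-6)

  expect_equal(count_density(0, g)$density_3d_mm3, 0)

  g2 <- acquisition_geometry(nx = 2048, ny = 2048, nz = 80)
  cd2 <- count_density(50, g2)
  expect_equal(cd2$density_3d_mm3, cd$density_3d_mm3 / 2)
  expect_equal(cd2$density_2d_mm2, cd$density_2d_mm2)
})

test_that("measure_cells produces one complete record per instance", {
  sc <- small_scene(seed = 64)
  cells <- measure_cells(sc$labels, stack_id = "s1")
  expect_s3_class(cells, "mg_cells")
  expect_equal(nrow(cells), nrow(sc$truth))
  expect_true(all(cells$volume_um3 <= cells$hull_volume_um3 + 1e-9))
  expect_true(all(cells$area_um2 <= cells$hull_area_um2 + 1e-9))
  expect_true(all(cells$perimeter_um >= cells$hull_perimeter_um - 1e-9))
  expect_true(all(cells$minor_axis_um <= cells$major_axis_um + 1e-12))
  expect_false(anyNA(cells$circularity))
  # volumes agree with the generator's ground truth exactly
  expect_equal(cells$volume_um3, sc$truth$true_volume_um3)
})
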