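test_that("an all-zero CD68 channel leaves every cell negative", {
  sc <- small_scene(seed = 81)
  cd68 <- array(0, dim(sc$labels))
  seg <- segment_cd68(cd68, sc$labels)
  expect_false(any(seg$mask))
  rec <- coloc_per_cell(seg$mask, sc$labels)
  expect_true(all(rec$cd68_volume_um3 == 0))
  expect_true(all(!rec$cd68_positive))
  expect_equal(coloc_summary(rec)$proportion_cd68_positive, 0)
})

test_that("noiseless rendering recovers the ground-truth puncta exactly", {
  g <- test_geometry(nx = 128, ny = 128, nz = 28)
  p <- scene_params(geometry = g, n_cells = 6, n_vessels = 0L,
                    psf_sigma_um = c(z = 0, y = 0, x = 0),
                    photon_scale = 0, read_noise_sd = 0)
  sc <- generate_scene(p, seed = 82)
  r <- render_stack(sc)
  seg <- segment_cd68(stack_channel(r$stack, 2), sc$labels)
  expect_equal(unname(as.logical(seg$mask)),
               unname(as.logical(sc$cd68_labels > 0L)))
  rec <- coloc_per_cell(seg$mask, sc$labels)
  expect_equal(rec$cd68_volume_um3, sc$truth$cd68_true_volume_um3)
})

test_that("per-cell CD68 volumes survive default noise within 25%", {
  sc <- small_scene(seed = 83, cd68_puncta_radius_um = c(1, 1.5))
  r <- render_stack(sc)
  seg <- segment_cd68(stack_channel(r$stack, 2), sc$labels)
  rec <- coloc_per_cell(seg$mask, sc$labels)
  truth <- sc$truth$cd68_true_volume_um3
  has <- truth > 0
  rel <- abs(rec$cd68_volume_um3[has] - truth[has]) / truth[has]
  expect_lt(median(rel), 0.25)
})

test_that("ratio bounds and the coloc invariants hold", {
  sc <- small_scene(seed = 84)
  r <- render_stack(sc)
  seg <- segment_cd68(stack_channel(r$stack, 2), sc$labels)
  rec <- coloc_per_cell(seg$mask, sc$labels)
  expect_true(all(rec$cd68_ratio >= 0 & rec$cd68_ratio <= 1))
  # per-cell CD68 never exceeds the total CD68 mask volume
  vv <- prod(attr(sc$labels, "spacing"))
  expect_lte(sum(rec$cd68_volume_um3), sum(seg$mask) * vv + 1e-9)

  # a cell fully covered by CD68 has ratio exactly 1
  labs <- array(0L, c(6, 6, 3))
  labs[2:4, 2:4, 1:2] <- 1L
  attr(labs, "spacing") <- c(1, 1, 1)
  full <- coloc_per_cell(labs > 0L, labs)
  expect_equal(full$cd68_ratio, 1)
  expect_true(full$cd68_positive)
})

test_that("raising the positivity threshold never raises the proportion", {
  sc <- small_scene(seed = 85)
  r <- render_stack(sc)
  seg <- segment_cd68(stack_channel(r$stack, 2), sc$labels)
  props <- vapply(c(0, 0.5, 2, 10, 50), function(pm) {
    coloc_summary(coloc_per_cell(seg$mask, sc$labels,
                                 positivity_min_um3 = pm))$
      proportion_cd68_positive
  }, numeric(1))
  expect_true(all(diff(props) <= 0))
})

test_that("the CD68-positive proportion is recovered near 90%", {
  props <- vapply(1:3, function(s) {
    sc <- generate_scene(scene_params(geometry = test_geometry(),
                                      n_cells = 30), seed = 860 + s)
    r <- render_stack(sc)
    seg <- segment_cd68(stack_channel(r$stack, 2), sc$labels)
    coloc_summary(coloc_per_cell(seg$mask, sc$labels))$
      proportion_cd68_positive
  }, numeric(1))
  expect_lt(abs(mean(props) - 90), 5)
})

test_that("stratification joins records and flags empty strata", {
  sc <- small_scene(seed = 87)
  r <- render_stack(sc)
  cells <- measure_cells(sc$labels, stack_id = "s1")
  seg <- segment_cd68(stack_channel(r$stack, 2), sc$labels)
  rec <- coloc_per_cell(seg$mask, sc$labels)
  rec$stack_id <- "s1"
  strat <- suppressWarnings(stratify_by_cd68(cells, rec, "control"))
  expect_equal(nrow(strat), nrow(cells))
  expect_s3_class(strat$cd68_status, "factor")
  expect_equal(strat$volume_um3, cells$volume_um3)

  # missing join keys are an explicit failure
  expect_error(stratify_by_cd68(cells, rec[-1, ], "control"), "label")

  # all-positive records leave the negative stratum empty, with a warning
  rec2 <- rec
  rec2$cd68_positive <- TRUE
  expect_warning(stratify_by_cd68(cells, rec2, "control"), "empty")
})

test_that("permuting group tags equalizes stratified means in expectation", {
  sc <- small_scene(seed = 88, n_cells = 10)
  cells <- measure_cells(sc$labels, stack_id = "s1")
  rec <- tibble::tibble(stack_id = "s1", label = cells$label,
                        cd68_positive = sc$truth$cd68_positive)
  set.seed(88)
  diffs <- replicate(200, {
    grp <- sample(c("control", "AD"), nrow(cells), replace = TRUE)
    strat <- suppressWarnings(stratify_by_cd68(cells, rec, grp))
    mm <- tapply(strat$volume_um3, strat$group, mean)
    if (length(mm) == 2) mm[[1]] - mm[[2]] else NA_real_
  })
  expect_lt(abs(mean(diffs, na.rm = TRUE)),
            2 * sd(diffs, na.rm = TRUE) / sqrt(sum(!is.na(diffs))) * 3)
})
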