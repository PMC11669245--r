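# a stack whose three classes have disjoint constant intensities, plus
# sparse labels drawn from each region
separable_case <- function(ny = 24, nx = 24, nz = 12, n = 40, seed = 31) {
  third <- nx %/% 3
  vol <- array(0, c(ny, nx, nz))
  vol[, seq_len(third), ] <- 0                       # background
  vol[, (third + 1):(2 * third), ] <- 128            # vasculature
  vol[, (2 * third + 1):nx, ] <- 255                 # microglia
  set.seed(seed)
  pickvox <- function(xrange, cls) {
    data.frame(y = sample(ny, n, TRUE), x = sample(xrange, n, TRUE),
               z = sample(nz, n, TRUE), class = cls)
  }
  df <- rbind(pickvox((2 * third + 1):nx, "microglia"),
              pickvox((third + 1):(2 * third), "vasculature"),
              pickvox(seq_len(third), "background"))
  df <- df[!duplicated(df[1:3]), ]
  list(vol = vol,
       labels = sparse_labels(df[1:3], df$class, c(ny, nx, nz)))
}

bank2 <- feature_bank(sigmas = c(0.7, 1.6))

test_that("intensity-separable classes are classified perfectly", {
  cs <- separable_case()
  half <- seq_len(nrow(cs$labels)) %% 2 == 0
  train <- cs$labels[!half, ]
  class(train) <- class(cs$labels)
  valid <- cs$labels[half, ]
  class(valid) <- class(cs$labels)
  clf <- train_voxel_classifier(cs$vol, train, bank2, seed = 1,
                                validation = valid)
  expect_equal(clf$validation_accuracy, 1)

  pm <- predict_probabilities(clf, cs$vol)
  # argmax class equals the sparse label at every labeled voxel
  idx <- microglia3d:::labels_linear_index(cs$labels, dim(cs$vol))
  flat <- matrix(unclass(pm), ncol = 3)
  pred <- dimnames(pm)[[4]][max.col(flat[idx, ], ties.method = "first")]
  expect_equal(pred, cs$labels$class)
})

test_that("probabilities are normalized at every voxel", {
  cs <- separable_case()
  clf <- train_voxel_classifier(cs$vol, cs$labels, bank2, seed = 1)
  pm <- predict_probabilities(clf, cs$vol)
  sums <- rowSums(matrix(unclass(pm), ncol = 3))
  expect_lt(max(abs(sums - 1)), 1e-6)
  expect_true(all(unclass(pm) >= 0 & unclass(pm) <= 1))
})

test_that("chunked prediction equals whole-stack prediction", {
  cs <- separable_case(ny = 16, nx = 16, nz = 8)
  clf <- train_voxel_classifier(cs$vol, cs$labels, bank2, seed = 1)
  pm1 <- predict_probabilities(clf, cs$vol, chunk_size = 1e6L)
  pm2 <- predict_probabilities(clf, cs$vol, chunk_size = 257L)
  expect_identical(unclass(pm1), unclass(pm2))
})

test_that("label order does not affect the trained model", {
  cs <- separable_case()
  shuffled <- cs$labels[rev(seq_len(nrow(cs$labels))), ]
  class(shuffled) <- class(cs$labels)
  clf1 <- train_voxel_classifier(cs$vol, cs$labels, bank2, seed = 7)
  clf2 <- train_voxel_classifier(cs$vol, shuffled, bank2, seed = 7)
  pm1 <- predict_probabilities(clf1, cs$vol)
  pm2 <- predict_probabilities(clf2, cs$vol)
  expect_equal(unclass(pm1), unclass(pm2), tolerance = 1e-12)
})

test_that("swapping training classes swaps the probability maps", {
  cs <- separable_case()
  swapped <- cs$labels
  swapped$class <- c(microglia = "vasculature", vasculature = "microglia",
                     background = "background")[swapped$class]
  class(swapped) <- class(cs$labels)
  clf1 <- train_voxel_classifier(cs$vol, cs$labels, bank2, seed = 3)
  clf2 <- train_voxel_classifier(cs$vol, swapped, bank2, seed = 3)
  pm1 <- predict_probabilities(clf1, cs$vol)
  pm2 <- predict_probabilities(clf2, cs$vol)
  expect_equal(microglia3d:::prob_class(pm1, "microglia"),
               microglia3d:::prob_class(pm2, "vasculature"),
               tolerance = 1e-12)
  expect_equal(microglia3d:::prob_class(pm1, "vasculature"),
               microglia3d:::prob_class(pm2, "microglia"),
               tolerance = 1e-12)
})

test_that("a class without labels fails naming the class", {
  cs <- separable_case()
  sub <- cs$labels[cs$labels$class != "vasculature", ]
  class(sub) <- class(cs$labels)
  expect_error(train_voxel_classifier(cs$vol, sub, bank2), "vasculature")
})

test_that("a mismatched feature bank at prediction time is rejected", {
  cs <- separable_case()
  clf <- train_voxel_classifier(cs$vol, cs$labels, bank2, seed = 1)
  other <- feature_bank(sigmas = c(0.7, 3.5))
  expect_error(predict_probabilities(clf, cs$vol, bank = other), "bank")
})

test_that("training on synthetic ground truth recovers microglia voxels", {
  sc <- small_scene(seed = 41)
  r <- render_stack(sc)
  vol <- stack_channel(r$stack, 1)
  clf <- train_voxel_classifier(vol, sample_sparse_labels(sc, 200, seed = 41),
                                feature_bank(), seed = 1)
  pm <- predict_probabilities(clf, vol)
  flat <- matrix(unclass(pm), ncol = 3)
  pred_microglia <- max.col(flat, ties.method = "first") == 1L
  truth_microglia <- as.logical(sc$labels > 0L)
  # voxel accuracy on the microglia class (ground truth as oracle)
  expect_gt(mean(pred_microglia == truth_microglia), 0.90)
})
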