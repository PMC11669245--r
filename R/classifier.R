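#' Sparse voxel labels
#'
#' Sparse annotations assign one of the three classes — `microglia`,
#' `vasculature`, `background` — to a small set of voxels; all other voxels
#' are unlabeled. Coordinates are 1-based `[y, x, z]` indices.
#'
#' @param coords Integer matrix / data frame with columns `y`, `x`, `z`.
#' @param class Character vector of class names, one per row.
#' @param dim Stack dimensions `(ny, nx, nz)` used to validate bounds.
#' @return A `sparse_labels` tibble with columns `y`, `x`, `z`, `class`.
#' @export
sparse_labels <- function(coords, class, dim) {
  coords <- as.data.frame(coords)
  stopifnot(all(c("y", "x", "z") %in% names(coords)))
  class <- as.character(class)
  if (nrow(coords) != length(class)) {
    abort("one class per labeled voxel required")
  }
  bad <- !class %in% c("microglia", "vasculature", "background")
  if (any(bad)) {
    abort(paste0("unknown class: ", paste(unique(class[bad]), collapse = ", ")))
  }
  if (any(coords$y < 1 | coords$y > dim[1] | coords$x < 1 |
            coords$x > dim[2] | coords$z < 1 | coords$z > dim[3])) {
    abort("labeled voxel coordinates outside stack bounds")
  }
  out <- tibble(y = as.integer(coords$y), x = as.integer(coords$x),
                z = as.integer(coords$z), class = class)
  if (anyDuplicated(out[c("y", "x", "z")])) {
    abort("each voxel may carry at most one class label")
  }
  class(out) <- c("sparse_labels", class(out))
  out
}

labels_linear_index <- function(labels, dim) {
  labels$y + dim[1] * (labels$x - 1L) + dim[1] * dim[2] * (labels$z - 1L)
}

#' Sample sparse training labels from ground truth
#'
#' Draws `n_per_class` voxels from each ground-truth class of a synthetic
#' scene — the simulated stand-in for expert sparse annotation. Half of the
#' background labels are drawn from the shell just outside objects (within
#' `shell_um` of a cell or vessel), emulating the corrective workflow in
#' which annotators label object borders explicitly; purely uniform
#' background sampling leaves the PSF halo ambiguous and dilates the
#' segmented cells.
#'
#' @param scene A [generate_scene()] result.
#' @param n_per_class Voxels per class (default 200).
#' @param seed Integer seed.
#' @param shell_um Thickness of the near-object background shell.
#' @return A [sparse_labels()] tibble.
#' @export
sample_sparse_labels <- function(scene, n_per_class = 200L, seed = 1L,
                                 shell_um = 1.5) {
  stopifnot(inherits(scene, "synthetic_scene"))
  with_seed(as.integer(seed), {
    d <- dim(scene$labels)
    sp <- attr(scene$labels, "spacing")
    bg <- scene$labels == 0L & !scene$vessel_mask
    pool <- list(
      microglia = which(scene$labels > 0L),
      vasculature = which(scene$vessel_mask),
      background = which(bg)
    )
    # background shell: bg voxels within shell_um of any object
    shell <- integer(0)
    if (any(bg) && !all(bg)) {
      d2 <- cpp_edt3(as.logical(bg), d[1], d[2], d[3], as.numeric(sp))
      shell <- which(bg & array(d2 > 0 & d2 <= shell_um^2, d))
    }
    draw <- function(idx, n) {
      if (length(idx) == 0L || n <= 0L) return(integer(0))
      idx[sample.int(length(idx), min(n, length(idx)))]
    }
    parts <- purrr::imap(pool, function(idx, cls) {
      if (length(idx) == 0L) {
        abort(sprintf("scene has no '%s' voxels to sample", cls))
      }
      take <- if (cls == "background" && length(shell) > 0L) {
        n_half <- n_per_class %/% 2L
        unique(c(draw(shell, n_half), draw(idx, n_per_class - n_half)))
      } else {
        draw(idx, n_per_class)
      }
      i0 <- take - 1L
      tibble(y = as.integer(i0 %% d[1]) + 1L,
             x = as.integer((i0 %/% d[1]) %% d[2]) + 1L,
             z = as.integer(i0 %/% (d[1] * d[2])) + 1L,
             class = cls)
    })
    df <- dplyr::bind_rows(parts)
    df <- df[!duplicated(df[c("y", "x", "z")]), ]
    sparse_labels(df[c("y", "x", "z")], df$class, d)
  })
}

#' Train the three-class random-forest voxel classifier
#'
#' Extracts the filter-bank features at the labeled voxels only and fits a
#' probability random forest over the classes microglia / vasculature /
#' background. Training is deterministic for a fixed seed.
#'
#' @param vol Single-channel 3D array (the IBA-1 channel).
#' @param labels A [sparse_labels()] tibble; every class must be present.
#' @param bank A [feature_bank()]; the same configuration must be used at
#'   prediction time.
#' @param n_trees Number of trees (default 100).
#' @param seed Integer seed.
#' @param validation Optional second [sparse_labels()] set; held-out accuracy
#'   is computed and stored.
#' @return A `voxel_classifier` carrying the fitted forest, the bank, the
#'   class levels, out-of-bag accuracy and (optionally) validation accuracy.
#' @export
train_voxel_classifier <- function(vol, labels, bank = feature_bank(),
                                   n_trees = 100L, seed = 1L,
                                   validation = NULL) {
  stopifnot(inherits(labels, "sparse_labels"))
  d <- dim(vol)
  classes <- c("microglia", "vasculature", "background")
  missing <- setdiff(classes, unique(labels$class))
  if (length(missing) > 0) {
    abort(paste0("no training labels for class: ",
                 paste(missing, collapse = ", ")))
  }
  idx <- labels_linear_index(labels, d)
  # canonical voxel order: training is invariant to label-row permutations
  ord <- order(idx)
  idx <- idx[ord]
  feat <- extract_features(vol, bank, voxels = idx)
  df <- as.data.frame(feat)
  df$.class <- factor(labels$class[ord], levels = classes)
  fit <- ranger::ranger(
    dependent.variable.name = ".class", data = df,
    num.trees = n_trees, probability = TRUE,
    seed = as.integer(seed), num.threads = 1L,
    respect.unordered.factors = "order"
  )
  out <- structure(
    list(forest = fit, bank = bank, classes = classes,
         n_trees = n_trees, seed = as.integer(seed),
         oob_error = fit$prediction.error),
    class = "voxel_classifier"
  )
  if (!is.null(validation)) {
    stopifnot(inherits(validation, "sparse_labels"))
    vidx <- labels_linear_index(validation, d)
    vfeat <- extract_features(vol, bank, voxels = vidx)
    pr <- predict(fit, data = as.data.frame(vfeat), num.threads = 1L)$predictions
    pred <- colnames(pr)[max.col(pr, ties.method = "first")]
    out$validation_accuracy <- mean(pred == validation$class)
  }
  out
}

#' @export
print.voxel_classifier <- function(x, ...) {
  cat(sprintf("<voxel_classifier> %d trees, %d features, OOB error %.3f\n",
              x$n_trees, length(feature_names(x$bank)), x$oob_error))
  if (!is.null(x$validation_accuracy)) {
    cat(sprintf("  held-out accuracy %.3f\n", x$validation_accuracy))
  }
  invisible(x)
}

#' Predict per-voxel class probabilities
#'
#' Applies the trained classifier to every voxel of a stack, in row chunks to
#' bound memory; chunked prediction is exactly identical to whole-stack
#' prediction. The output probabilities are non-negative and sum to one at
#' every voxel.
#'
#' @param classifier A [train_voxel_classifier()] result.
#' @param vol Single-channel 3D array.
#' @param bank Optional [feature_bank()]; must equal the training bank
#'   (supplying a different one is an error).
#' @param chunk_size Voxels per prediction chunk.
#' @return A `probability_map`: array `[y, x, z, class]` over the classes
#'   `microglia`, `vasculature`, `background`, with voxel spacing attached.
#' @export
predict_probabilities <- function(classifier, vol, bank = NULL,
                                  chunk_size = 500000L) {
  stopifnot(inherits(classifier, "voxel_classifier"))
  if (!is.null(bank) && !identical(unclass(bank), unclass(classifier$bank))) {
    abort("feature bank differs from the one used in training")
  }
  bank <- classifier$bank
  d <- dim(vol)
  feat <- extract_features(vol, bank)
  n <- nrow(feat)
  probs <- matrix(NA_real_, n, 3,
                  dimnames = list(NULL, classifier$classes))
  starts <- seq(1L, n, by = as.integer(chunk_size))
  for (s in starts) {
    e <- min(s + chunk_size - 1L, n)
    pr <- predict(classifier$forest,
                  data = as.data.frame(feat[s:e, , drop = FALSE]),
                  num.threads = 1L)$predictions
    probs[s:e, ] <- pr[, classifier$classes, drop = FALSE]
  }
  out <- array(probs, c(d, 3L),
               dimnames = list(NULL, NULL, NULL, classifier$classes))
  attr(out, "spacing") <- attr(vol, "spacing")
  class(out) <- "probability_map"
  out
}

#' @export
print.probability_map <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<probability_map> %d x %d x %d voxels x %d classes\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

# class plane of a probability map as a 3D array
prob_class <- function(pmap, class) {
  d <- dim(pmap)
  cls <- dimnames(pmap)[[4]]
  k <- if (is.character(class)) match(class, cls) else class
  if (is.na(k)) abort("unknown probability class")
  out <- unclass(pmap)[, , , k, drop = FALSE]
  dim(out) <- d[1:3]
  attr(out, "spacing") <- attr(pmap, "spacing")
  out
}
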