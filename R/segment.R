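#' Smooth the microglia probability field
#'
#' Gaussian smoothing (default sigma = 1 voxel) of the microglia class
#' probability, the first post-processing step after classification.
#' `sigma = 0` is the identity; values stay within `[0, 1]`.
#'
#' @param pmap A `probability_map` or a plain 3D field in `[0, 1]`.
#' @param sigma Gaussian sigma in voxels, `>= 0`.
#' @return 3D array, same shape, spacing preserved.
#' @export
smooth_probability <- function(pmap, sigma = 1) {
  if (length(sigma) != 1 || sigma < 0) abort("sigma must be a scalar >= 0")
  field <- if (inherits(pmap, "probability_map")) {
    prob_class(pmap, "microglia")
  } else {
    pmap
  }
  if (sigma == 0) return(field)
  out <- gauss3(field, c(sigma, sigma, sigma))
  attr(out, "spacing") <- attr(field, "spacing")
  out
}

#' Otsu threshold of a field
#'
#' Histogram threshold (256 bins over the value range) maximizing the
#' between-class variance; the foreground mask is `field > threshold`.
#' Constant fields carry no threshold and are an error.
#'
#' @param field Numeric array (any shape).
#' @param n_bins Number of histogram bins (default 256).
#' @return List with `mask` (logical, same shape) and `threshold`.
#' @export
otsu_threshold <- function(field, n_bins = 256L) {
  v <- as.numeric(field)
  rng <- range(v)
  if (!is.finite(rng[1]) || !is.finite(rng[2])) abort("field must be finite")
  if (rng[1] == rng[2]) {
    abort("field is constant: no Otsu threshold exists")
  }
  h <- graphics::hist(v, breaks = seq(rng[1], rng[2], length.out = n_bins + 1L),
                      plot = FALSE)
  counts <- as.numeric(h$counts)
  centers <- h$mids
  w1 <- cumsum(counts)
  w2 <- sum(counts) - w1
  m1 <- cumsum(counts * centers) / pmax(w1, 1)
  m2 <- (sum(counts * centers) - cumsum(counts * centers)) / pmax(w2, 1)
  # split after bin t: classes {1..t}, {t+1..n}
  valid <- seq_len(n_bins - 1L)
  sigma_b <- w1[valid] * w2[valid] * (m1[valid] - m2[valid])^2
  t_idx <- valid[which.max(sigma_b)]
  thr <- centers[t_idx]
  mask <- field > thr
  attr(mask, "spacing") <- attr(field, "spacing")
  list(mask = mask, threshold = thr)
}

#' Exclude high-probability vasculature voxels from a mask
#'
#' Removes from the foreground mask every voxel whose vasculature-class
#' probability is at or above `v_threshold`. Vessels fluoresce in the same
#' channel as IBA-1, so this step removes most vessel-driven false positives
#' before instance separation.
#'
#' @param mask Logical 3D array.
#' @param pmap A `probability_map`.
#' @param v_threshold Probability cutoff in `(0, 1]` (default 0.5).
#' @return Logical array, a subset of `mask`.
#' @export
exclude_vasculature <- function(mask, pmap, v_threshold = 0.5) {
  if (v_threshold <= 0 || v_threshold > 1) {
    abort("v_threshold must be in (0, 1]")
  }
  pv <- prob_class(pmap, "vasculature")
  out <- mask & !(pv >= v_threshold)
  attr(out, "spacing") <- attr(mask, "spacing") %||% attr(pmap, "spacing")
  out
}

#' Separate individual microglia by marker-based watershed
#'
#' Splits the binary microglia mask into instances. The elevation map is the
#' Sobel gradient magnitude of the binarized mask (index-space gradients);
#' markers are the regional maxima of the Gaussian-smoothed Euclidean
#' distance transform, kept only where the distance exceeds
#' `marker_min_distance_um` (suppresses spurious seeds on thin processes) and
#' thinned to a minimum mutual separation. Flooding is deterministic:
#' first-in-first-out within equal elevation. Mask components that receive no
#' marker become their own labels, so the labels always partition the mask.
#'
#' @param mask Logical 3D array with a `spacing` attribute (or pass
#'   `spacing`).
#' @param spacing Voxel spacing `(y, x, z)` in um.
#' @param marker_smooth_sigma Smoothing sigma (voxels) for the distance map.
#' @param marker_min_separation_um Minimum distance between markers.
#' @param marker_min_distance_um Minimum distance-transform value for a
#'   marker.
#' @return Integer `label_volume` array: 0 outside the mask, labels
#'   `1..K` (compacted) inside; 26-connectivity; spacing attached.
#' @export
separate_instances <- function(mask, spacing = NULL,
                               marker_smooth_sigma = 2,
                               marker_min_separation_um = 5,
                               marker_min_distance_um = 2.5) {
  spacing <- spacing %||% spacing_of(mask)
  d <- dim(mask)
  if (!any(mask)) {
    out <- array(0L, d)
    attr(out, "spacing") <- spacing
    class(out) <- "label_volume"
    return(out)
  }
  dist2 <- cpp_edt3(as.logical(mask), d[1], d[2], d[3], as.numeric(spacing))
  dist <- sqrt(pmax(dist2, 0))
  dim(dist) <- d
  sm <- gauss3(dist, rep(marker_smooth_sigma, 3))
  sm[!mask] <- 0

  peaks <- cpp_regmax3(as.numeric(sm), as.logical(mask), d[1], d[2], d[3])
  peaks <- peaks & (as.numeric(dist) >= marker_min_distance_um)
  dim(peaks) <- d
  markers <- cpp_label3(as.logical(peaks), d[1], d[2], d[3], 26L)
  n_mark <- attr(markers, "n_labels")

  if (n_mark > 1L) {
    # thin markers closer than the minimum separation, strongest first
    idx <- which(markers > 0L)
    lab <- markers[idx]
    coord <- arrayInd(idx, d)
    phys <- cbind(coord[, 1] * spacing[1], coord[, 2] * spacing[2],
                  coord[, 3] * spacing[3])
    cent <- rowsum(phys, lab) / as.numeric(table(lab))
    peak_val <- vapply(split(sm[idx], lab), max, numeric(1))
    ord <- order(-peak_val, as.integer(names(peak_val)))
    keep <- logical(length(ord))
    kept_pts <- NULL
    for (k in ord) {
      p <- cent[k, , drop = FALSE]
      if (is.null(kept_pts) ||
            min(sqrt(rowSums(sweep(kept_pts, 2, p)^2))) >=
              marker_min_separation_um) {
        keep[k] <- TRUE
        kept_pts <- rbind(kept_pts, p)
      }
    }
    kept_ids <- which(keep)
    remap <- integer(n_mark)
    remap[kept_ids] <- seq_along(kept_ids)
    mv <- markers
    mv[mv > 0L] <- remap[mv[mv > 0L]]
    markers <- mv
  }

  elev <- cpp_sobel3(as.numeric(mask), d[1], d[2], d[3])
  labels <- cpp_watershed3(elev, as.integer(markers), as.logical(mask),
                           d[1], d[2], d[3])
  dim(labels) <- d

  # orphan components (no marker) become their own instances
  orphan <- mask & labels == 0L
  if (any(orphan)) {
    extra <- cpp_label3(as.logical(orphan), d[1], d[2], d[3], 26L)
    offset <- max(labels)
    labels[orphan] <- extra[orphan] + offset
  }
  labels <- compact_labels(labels)
  attr(labels, "spacing") <- spacing
  class(labels) <- "label_volume"
  labels
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<label_volume> %d x %d x %d voxels, %d instance(s)\n",
              d[1], d[2], d[3], n_labels(x)))
  invisible(x)
}

#' Label-volume utilities
#'
#' `n_labels()` counts instances; `compact_labels()` renumbers surviving
#' labels to `1..K` preserving order; `label_sizes()` tabulates voxel counts.
#'
#' @param labels Integer label array.
#' @return See each description.
#' @export
n_labels <- function(labels) {
  m <- max(labels)
  if (m == 0L) 0L else length(unique(labels[labels > 0L]))
}

#' @rdname n_labels
#' @export
compact_labels <- function(labels) {
  atts <- attributes(labels)
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) == 0L || identical(ids, seq_along(ids))) {
    return(labels)
  }
  remap <- integer(max(ids))
  remap[ids] <- seq_along(ids)
  pos <- labels > 0L
  labels[pos] <- remap[labels[pos]]
  attributes(labels) <- atts
  labels
}

#' @rdname n_labels
#' @export
label_sizes <- function(labels) {
  m <- max(labels)
  if (m == 0L) return(integer(0))
  tabulate(labels[labels > 0L], nbins = m)
}

#' Remove labels smaller than typical microglia
#'
#' Drops instances whose physical volume is below `min_volume_um3`
#' (default 100 um^3) and compacts the surviving ids. The rejection report
#' lists every label with its volume and fate.
#'
#' @param labels A `label_volume` (or integer array with spacing).
#' @param min_volume_um3 Minimum instance volume, um^3; `0` is the identity.
#' @param spacing Voxel spacing, if not carried by `labels`.
#' @return The filtered `label_volume`, with the report attached as
#'   `attr(, "size_filter_report")` (a tibble: `label`, `volume_um3`,
#'   `kept`).
#' @export
size_filter <- function(labels, min_volume_um3 = 100, spacing = NULL) {
  if (min_volume_um3 < 0) abort("min_volume_um3 must be >= 0")
  spacing <- spacing %||% spacing_of(labels)
  vv <- prod(spacing)
  sizes <- label_sizes(labels)
  vols <- sizes * vv
  kept <- vols >= min_volume_um3
  report <- tibble(label = seq_along(vols), volume_um3 = vols, kept = kept)
  if (any(!kept)) {
    drop <- which(!kept)
    pos <- labels %in% drop
    labels[pos] <- 0L
    labels <- compact_labels(labels)
  }
  attr(labels, "spacing") <- spacing
  attr(labels, "size_filter_report") <- report
  class(labels) <- "label_volume"
  labels
}

#' Apply expert accept/reject decisions to instances
#'
#' The manual quality-control contract: every decision references an
#' existing label; rejected labels are zeroed and ids compacted. The decision
#' log travels with the result.
#'
#' @param labels A `label_volume`.
#' @param decisions Data frame with columns `label` and `accept` (logical);
#'   labels not listed are kept. An empty decision set is the identity.
#' @return Filtered `label_volume` with `attr(, "qc_log")`.
#' @export
qc_review <- function(labels, decisions = NULL) {
  spacing <- attr(labels, "spacing")
  ids <- seq_len(max(0L, max(labels)))
  if (is.null(decisions) || nrow(decisions) == 0L) {
    attr(labels, "qc_log") <- tibble(label = integer(0), accept = logical(0))
    return(labels)
  }
  decisions <- as_tibble(decisions)
  stopifnot(all(c("label", "accept") %in% names(decisions)))
  unknown <- setdiff(decisions$label, ids)
  if (length(unknown) > 0) {
    abort(paste0("decisions reference nonexistent label(s): ",
                 paste(unknown, collapse = ", ")))
  }
  reject <- decisions$label[!decisions$accept]
  if (length(reject) > 0) {
    labels[labels %in% reject] <- 0L
    labels <- compact_labels(labels)
  }
  attr(labels, "spacing") <- spacing
  attr(labels, "qc_log") <- decisions
  class(labels) <- "label_volume"
  labels
}

#' Run the full mask-to-instances post-processing chain
#'
#' Convenience wrapper: smooth the microglia probability, Otsu-threshold it,
#' exclude vasculature, separate instances by watershed and size-filter the
#' result — the standard post-classification sequence.
#'
#' @param pmap A `probability_map`.
#' @param smooth_sigma,v_threshold,min_volume_um3 Stage parameters.
#' @param ... Passed on to [separate_instances()].
#' @return A `label_volume`.
#' @export
segment_microglia <- function(pmap, smooth_sigma = 1, v_threshold = 0.5,
                              min_volume_um3 = 100, ...) {
  sm <- smooth_probability(pmap, smooth_sigma)
  ot <- otsu_threshold(sm)
  mask <- exclude_vasculature(ot$mask, pmap, v_threshold)
  labels <- separate_instances(mask, ...)
  size_filter(labels, min_volume_um3)
}
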