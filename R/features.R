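#' Multi-scale filter bank for voxel classification
#'
#' The feature set used by the voxel classifier: raw intensity plus, at each
#' scale, Gaussian smoothing, Laplacian of Gaussian, Gaussian gradient
#' magnitude, difference of Gaussians, the three structure-tensor eigenvalues
#' and the three Hessian-of-Gaussian eigenvalues. The default scales are
#' sigma = 0.3, 0.7, 1.0, 1.6, 3.5, 5.0 and 10 in voxel units.
#'
#' Sigmas are interpreted in index space (isotropic in voxels) even though
#' voxels are typically anisotropic; set `anisotropy_correction = TRUE` to
#' scale the z sigma by `dx/dz` instead. The structure tensor uses an inner
#' (gradient) scale of `0.5 * sigma` for each outer (integration) scale. The
#' difference of Gaussians at sigma_i is `G(sigma_{i+1}) - G(sigma_i)`
#' (with `1.6 * sigma` as the upper scale for the last sigma). All filters
#' use reflective boundary handling. Eigenvalues are sorted descending so the
#' features are rotation-consistent.
#'
#' @param sigmas Strictly increasing positive scales, voxel units.
#' @param filters Subset of the six filter families to compute.
#' @param anisotropy_correction Scale the axial sigma by `dx/dz`? Default
#'   `FALSE`.
#' @return A `feature_bank` object; `feature_names(bank)` lists the feature
#'   vector layout, whose length is fixed once configured.
#' @export
feature_bank <- function(sigmas = c(0.3, 0.7, 1.0, 1.6, 3.5, 5.0, 10),
                         filters = c("gaussian_smoothing",
                                     "laplacian_of_gaussian",
                                     "gaussian_gradient_magnitude",
                                     "difference_of_gaussians",
                                     "structure_tensor_eigenvalues",
                                     "hessian_of_gaussian_eigenvalues"),
                         anisotropy_correction = FALSE) {
  if (length(sigmas) < 1 || any(sigmas <= 0) || is.unsorted(sigmas, strictly = TRUE)) {
    abort("sigmas must be strictly increasing and positive")
  }
  filters <- match.arg(filters, several.ok = TRUE)
  structure(
    list(sigmas = as.numeric(sigmas), filters = filters,
         anisotropy_correction = isTRUE(anisotropy_correction)),
    class = "feature_bank"
  )
}

#' @rdname feature_bank
#' @param bank A `feature_bank`.
#' @export
feature_names <- function(bank) {
  stopifnot(inherits(bank, "feature_bank"))
  nm <- "intensity"
  per <- c(gaussian_smoothing = 1, laplacian_of_gaussian = 1,
           gaussian_gradient_magnitude = 1, difference_of_gaussians = 1,
           structure_tensor_eigenvalues = 3,
           hessian_of_gaussian_eigenvalues = 3)
  for (f in bank$filters) {
    for (s in bank$sigmas) {
      k <- per[[f]]
      suffix <- if (k == 1) "" else paste0("_ev", seq_len(k))
      nm <- c(nm, sprintf("%s_s%g%s", f, s, suffix))
    }
  }
  nm
}

#' @export
print.feature_bank <- function(x, ...) {
  cat(sprintf("<feature_bank> %d features: %d filter families x %d sigmas (+ intensity)\n",
              length(feature_names(x)), length(x$filters), length(x$sigmas)))
  cat("  sigmas:", paste(x$sigmas, collapse = ", "), "(voxel units)\n")
  invisible(x)
}

# sigma triple (y, x, z) in voxels for a nominal scale
bank_sigma_vox <- function(bank, s, spacing) {
  sz <- if (bank$anisotropy_correction && !is.null(spacing)) {
    s * spacing[["x"]] / spacing[["z"]]
  } else {
    s
  }
  c(s, s, sz)
}

gauss3 <- function(vol, sigma_vox, order = c(0L, 0L, 0L)) {
  d <- dim(vol)
  out <- cpp_gauss3(as.numeric(vol), d[1], d[2], d[3],
                    as.numeric(sigma_vox), as.integer(order))
  dim(out) <- d
  out
}

#' Extract per-voxel filter-bank features
#'
#' Computes the configured feature vector for every voxel of a
#' single-channel stack, or only for a subset of voxels (used when training
#' on sparse labels, where materializing the dense feature matrix would be
#' wasteful).
#'
#' @param vol 3D numeric array `[y, x, z]`.
#' @param bank A [feature_bank()].
#' @param voxels Optional integer vector of linear voxel indices; if given,
#'   only those rows are returned.
#' @param spacing Optional voxel spacing (used only when the bank applies
#'   its anisotropy correction).
#' @return Numeric matrix, one row per (selected) voxel, with feature names
#'   as column names. Deterministic: repeated calls are bit-identical.
#' @export
extract_features <- function(vol, bank, voxels = NULL, spacing = NULL) {
  stopifnot(inherits(bank, "feature_bank"))
  d <- dim(vol)
  if (length(d) != 3L) abort("extract_features needs a single-channel 3D array")
  if (is.null(spacing)) spacing <- attr(vol, "spacing")
  nm <- feature_names(bank)
  n <- if (is.null(voxels)) prod(d) else length(voxels)
  out <- matrix(NA_real_, n, length(nm), dimnames = list(NULL, nm))
  pick <- function(a) if (is.null(voxels)) as.numeric(a) else a[voxels]
  out[, 1] <- pick(vol)
  col <- 1L

  sig <- bank$sigmas
  # cache plain smoothings for the DoG pairs
  smooth_cache <- new.env(parent = emptyenv())
  get_smooth <- function(s) {
    key <- format(s, digits = 12)
    if (!is.null(smooth_cache[[key]])) return(smooth_cache[[key]])
    v <- gauss3(vol, bank_sigma_vox(bank, s, spacing))
    smooth_cache[[key]] <- v
    v
  }

  for (f in bank$filters) {
    for (i in seq_along(sig)) {
      s <- sig[i]
      sv <- bank_sigma_vox(bank, s, spacing)
      if (f == "gaussian_smoothing") {
        out[, col + 1L] <- pick(get_smooth(s))
        col <- col + 1L
      } else if (f == "laplacian_of_gaussian") {
        v <- gauss3(vol, sv, c(2L, 0L, 0L)) +
          gauss3(vol, sv, c(0L, 2L, 0L)) +
          gauss3(vol, sv, c(0L, 0L, 2L))
        out[, col + 1L] <- pick(v)
        col <- col + 1L
      } else if (f == "gaussian_gradient_magnitude") {
        v <- sqrt(gauss3(vol, sv, c(1L, 0L, 0L))^2 +
                    gauss3(vol, sv, c(0L, 1L, 0L))^2 +
                    gauss3(vol, sv, c(0L, 0L, 1L))^2)
        out[, col + 1L] <- pick(v)
        col <- col + 1L
      } else if (f == "difference_of_gaussians") {
        s2 <- if (i < length(sig)) sig[i + 1L] else 1.6 * s
        out[, col + 1L] <- pick(get_smooth(s2) - get_smooth(s))
        col <- col + 1L
      } else if (f == "structure_tensor_eigenvalues") {
        inner <- bank_sigma_vox(bank, 0.5 * s, spacing)
        gy <- gauss3(vol, inner, c(1L, 0L, 0L))
        gx <- gauss3(vol, inner, c(0L, 1L, 0L))
        gz <- gauss3(vol, inner, c(0L, 0L, 1L))
        m6 <- cbind(
          pick(gauss3(gx * gx, sv)), pick(gauss3(gx * gy, sv)),
          pick(gauss3(gx * gz, sv)), pick(gauss3(gy * gy, sv)),
          pick(gauss3(gy * gz, sv)), pick(gauss3(gz * gz, sv))
        )
        ev <- cpp_sym3_eigenvalues(m6)
        out[, col + 1:3] <- ev
        col <- col + 3L
      } else if (f == "hessian_of_gaussian_eigenvalues") {
        m6 <- cbind(
          pick(gauss3(vol, sv, c(0L, 2L, 0L))),  # xx
          pick(gauss3(vol, sv, c(1L, 1L, 0L))),  # xy
          pick(gauss3(vol, sv, c(0L, 1L, 1L))),  # xz
          pick(gauss3(vol, sv, c(2L, 0L, 0L))),  # yy
          pick(gauss3(vol, sv, c(1L, 0L, 1L))),  # yz
          pick(gauss3(vol, sv, c(0L, 0L, 2L)))   # zz
        )
        ev <- cpp_sym3_eigenvalues(m6)
        out[, col + 1:3] <- ev
        col <- col + 3L
      }
    }
  }
  out
}
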