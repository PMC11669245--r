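#' Parameters for a synthetic retinal-microglia scene
#'
#' Describes one simulated confocal field: how many microglia, their volume
#' distribution, CD68 content, vasculature, optics and noise. Group-level
#' defaults follow the reported group means: control microglia average
#' 1085 um^3 and AD microglia 1754 um^3, and roughly 90% of cells carry CD68
#' puncta (the AD default doubles the per-cell punctum count, matching the
#' direction of the reported CD68-load increase).
#'
#' Each simulated cell is a soma (axis-aligned ellipsoid) plus 2-6 tubular
#' processes grown as persistent random walks. The `amoeboid` parameter in
#' `[0, 1]` trades process volume for soma volume at fixed total volume, so a
#' scene can span the ramified-to-amoeboid morphology spectrum.
#'
#' @param geometry An [acquisition_geometry()].
#' @param n_cells Number of microglia to place.
#' @param group `"control"` or `"AD"`; picks volume / CD68 defaults.
#' @param mean_volume Mean true cell volume in um^3. Default 1085 (control)
#'   or 1754 (AD).
#' @param volume_cv Coefficient of variation of per-cell volumes (gamma
#'   distributed, then renormalized so the sample mean equals `mean_volume`).
#' @param amoeboid_range Per-cell amoeboid parameter is drawn uniformly from
#'   this range; both groups share it by default (no built-in shape effect).
#' @param n_process_range,process_radius_um Range of process count and radius.
#' @param cd68_fraction Fraction of cells flagged CD68-positive.
#' @param cd68_puncta_range Range of puncta per positive cell (before the
#'   group multiplier).
#' @param cd68_puncta_multiplier Multiplies the punctum count (default 2 for
#'   AD).
#' @param cd68_puncta_radius_um Range of punctum radius in um.
#' @param min_spacing_um Minimum distance between cell centroids (rejection
#'   sampling).
#' @param n_vessels Number of vessel tubes crossing the field.
#' @param vessel_radius_um Range of vessel radius in um.
#' @param vessel_bleed If `TRUE` (default) vessels fluoresce into the IBA-1
#'   channel, as they do in the real acquisitions.
#' @param intensity Named list: `background`, `cell`, `vessel`,
#'   `cd68_background`, `puncta` mean signal levels (arbitrary units).
#' @param psf_sigma_um Gaussian PSF sigma `(z, y, x)` in um.
#' @param photon_scale Photons per intensity unit for the Poisson stage;
#'   0 disables shot noise.
#' @param read_noise_sd Additive Gaussian read noise (intensity units);
#'   0 disables it.
#' @return A `scene_params` object.
#' @seealso [generate_scene()], [render_stack()]
#' @export
scene_params <- function(geometry = acquisition_geometry(),
                         n_cells = 30L,
                         group = c("control", "AD"),
                         mean_volume = NULL,
                         volume_cv = 0.3,
                         amoeboid_range = c(0.2, 0.8),
                         n_process_range = c(2L, 6L),
                         process_radius_um = c(0.5, 1.0),
                         cd68_fraction = 0.9,
                         cd68_puncta_range = c(1L, 8L),
                         cd68_puncta_multiplier = NULL,
                         cd68_puncta_radius_um = c(0.5, 1.5),
                         min_spacing_um = 12,
                         n_vessels = 2L,
                         vessel_radius_um = c(2, 4),
                         vessel_bleed = TRUE,
                         intensity = list(background = 100, cell = 500,
                                          vessel = 700, cd68_background = 80,
                                          puncta = 600),
                         psf_sigma_um = c(z = 1.0, y = 0.3, x = 0.3),
                         photon_scale = 0.2,
                         read_noise_sd = 10) {
  group <- match.arg(group)
  if (is.null(mean_volume)) {
    mean_volume <- if (group == "AD") 1754 else 1085
  }
  if (is.null(cd68_puncta_multiplier)) {
    cd68_puncta_multiplier <- if (group == "AD") 2 else 1
  }
  stopifnot(inherits(geometry, "acq_geometry"))
  n_cells <- as.integer(n_cells)
  if (n_cells < 0L) abort("n_cells must be >= 0")
  if (mean_volume <= 0) abort("mean_volume must be positive")
  if (volume_cv < 0 || volume_cv > 1) abort("volume_cv must be in [0, 1]")
  if (cd68_fraction < 0 || cd68_fraction > 1) {
    abort("cd68_fraction must be in [0, 1]")
  }
  if (photon_scale < 0 || read_noise_sd < 0) {
    abort("noise parameters must be non-negative")
  }
  structure(
    list(geometry = geometry, n_cells = n_cells, group = group,
         mean_volume = mean_volume, volume_cv = volume_cv,
         amoeboid_range = amoeboid_range,
         n_process_range = as.integer(n_process_range),
         process_radius_um = process_radius_um,
         cd68_fraction = cd68_fraction,
         cd68_puncta_range = as.integer(cd68_puncta_range),
         cd68_puncta_multiplier = cd68_puncta_multiplier,
         cd68_puncta_radius_um = cd68_puncta_radius_um,
         min_spacing_um = min_spacing_um,
         n_vessels = as.integer(n_vessels),
         vessel_radius_um = vessel_radius_um,
         vessel_bleed = isTRUE(vessel_bleed),
         intensity = intensity,
         psf_sigma_um = psf_sigma_um,
         photon_scale = photon_scale,
         read_noise_sd = read_noise_sd),
    class = "scene_params"
  )
}

# run code with a private, restored RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# unit vector uniform on the sphere
runif_sphere <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

#' Generate a synthetic scene with ground truth
#'
#' Places microglia by rejection sampling (minimum centroid spacing), grows
#' their soma + process morphology, assigns CD68 puncta, lays vessel tubes,
#' and voxelizes everything into a ground-truth instance label volume. Voxel
#' ownership is first-come by cell index; vessels claim only voxels not owned
#' by any cell, so the foreground is partitioned with no overlap.
#'
#' The drawn per-cell target volumes are renormalized so their mean equals
#' `params$mean_volume` exactly; the voxelized (true) volumes then match the
#' requested group mean up to digitization error.
#'
#' @param params A [scene_params()] object.
#' @param seed Integer seed; scenes are exactly reproducible from
#'   `(params, seed)`.
#' @return A `synthetic_scene` with elements `params`, `cells` (per-cell
#'   specs), `vessels`, `labels` (ground-truth instance labels, `[y, x, z]`),
#'   `vessel_mask`, `cd68_labels` (puncta voxels, valued by owning cell), and
#'   `truth` (a tibble of per-cell true volumes and CD68 content).
#' @export
generate_scene <- function(params, seed = 1L) {
  stopifnot(inherits(params, "scene_params"))
  with_seed(as.integer(seed), generate_scene_impl(params, as.integer(seed)))
}

generate_scene_impl <- function(params, seed) {
  g <- params$geometry
  sp <- geom_spacing(g)
  fx <- g$nx * g$dx; fy <- g$ny * g$dy; fz <- g$nz * g$dz
  n <- params$n_cells

  cells <- list()
  if (n > 0L) {
    # per-cell target volumes: gamma with requested CV, mean renormalized
    cv <- params$volume_cv
    vols <- if (cv > 0) {
      rgamma(n, shape = 1 / cv^2, scale = params$mean_volume * cv^2)
    } else {
      rep(params$mean_volume, n)
    }
    vols <- vols * params$mean_volume / mean(vols)

    amoeboid <- runif(n, params$amoeboid_range[1], params$amoeboid_range[2])
    soma_frac <- 0.65 + 0.3 * amoeboid
    soma_vol <- soma_frac * vols
    soma_r <- (3 * soma_vol / (4 * pi))^(1 / 3)

    # placement with minimum spacing and a soma-sized margin
    centroids <- matrix(NA_real_, n, 3)  # (y, x, z) um
    max_attempts <- 500L * n
    attempts <- 0L
    for (i in seq_len(n)) {
      margin <- soma_r[i] * 1.25 + 0.5
      if (2 * margin >= fz || 2 * margin >= fx || 2 * margin >= fy) {
        abort(sprintf(
          "cell soma (radius %.1f um) cannot fit inside the %.0f x %.0f x %.0f um field",
          soma_r[i], fx, fy, fz))
      }
      repeat {
        attempts <- attempts + 1L
        if (attempts > max_attempts) {
          abort(sprintf(
            paste0("unsatisfiable packing: could not place %d cells with ",
                   "min spacing %.1f um in a %.0f x %.0f x %.0f um field"),
            n, params$min_spacing_um, fx, fy, fz))
        }
        cand <- c(runif(1, margin, fy - margin),
                  runif(1, margin, fx - margin),
                  runif(1, margin, fz - margin))
        if (i == 1L) break
        d2 <- colSums((t(centroids[seq_len(i - 1L), , drop = FALSE]) - cand)^2)
        if (min(d2) >= params$min_spacing_um^2) break
      }
      centroids[i, ] <- cand
    }

    cd68_n <- round(params$cd68_fraction * n)
    cd68_pos <- seq_len(n) %in% sample.int(n, cd68_n)

    for (i in seq_len(n)) {
      # soma: axis-aligned ellipsoid, radii jittered at fixed volume
      jit <- runif(3, 0.85, 1.18)
      jit <- jit / prod(jit)^(1 / 3)
      radii <- soma_r[i] * jit  # (ry, rx, rz)

      # processes: persistent random-walk tubes from the soma surface
      n_proc <- sample(seq(params$n_process_range[1],
                           params$n_process_range[2]), 1)
      proc_vol_total <- (1 - soma_frac[i]) * vols[i]
      w <- rgamma(n_proc, shape = 2)
      proc_vols <- proc_vol_total * w / sum(w)
      processes <- vector("list", n_proc)
      for (p in seq_len(n_proc)) {
        pr <- runif(1, params$process_radius_um[1], params$process_radius_um[2])
        len <- proc_vols[p] / (pi * pr^2)
        if (len > 50) {  # cap length; widen the tube to keep the volume
          pr <- sqrt(proc_vols[p] / (pi * 50))
          len <- 50
        }
        dir <- runif_sphere()
        start <- centroids[i, ] + dir * radii * 0.9
        step <- 0.75
        n_steps <- max(2L, ceiling(len / step))
        path <- matrix(NA_real_, n_steps, 3)
        pos <- start
        d <- dir
        for (s in seq_len(n_steps)) {
          path[s, ] <- pos
          d <- d + 0.35 * rnorm(3)
          d <- d / sqrt(sum(d^2))
          pos <- pos + d * step
          pos <- pmin(pmax(pos, pr + 0.01),
                      c(fy, fx, fz) - pr - 0.01)
        }
        processes[[p]] <- list(path = path, radius = pr)
      }

      # CD68 puncta inside the soma
      puncta <- NULL
      if (cd68_pos[i]) {
        np <- sample(seq(params$cd68_puncta_range[1],
                         params$cd68_puncta_range[2]), 1)
        np <- min(16L, ceiling(np * params$cd68_puncta_multiplier))
        puncta <- matrix(NA_real_, np, 4)  # (y, x, z, r)
        for (q in seq_len(np)) {
          u <- runif_sphere() * runif(1)^(1 / 3)
          ctr <- centroids[i, ] + u * radii * 0.6
          r <- runif(1, params$cd68_puncta_radius_um[1],
                     params$cd68_puncta_radius_um[2])
          puncta[q, ] <- c(ctr, min(r, 0.8 * min(radii)))
        }
      }

      cells[[i]] <- list(
        id = i, centroid = centroids[i, ], target_volume = vols[i],
        amoeboid = amoeboid[i], soma_radii = radii,
        processes = processes, cd68_positive = cd68_pos[i], puncta = puncta
      )
    }
  }

  # vessels: gently wavy tubes crossing the field laterally
  vessels <- list()
  if (params$n_vessels > 0L) {
    for (v in seq_len(params$n_vessels)) {
      r <- runif(1, params$vessel_radius_um[1], params$vessel_radius_um[2])
      horiz <- runif(1) < 0.5
      tpos <- runif(1, 0.15, 0.85)
      zpos <- runif(1, 0.25, 0.75) * fz
      amp <- runif(1, 2, 8)
      phase <- runif(1, 0, 2 * pi)
      s <- seq(0, 1, length.out = 200)
      if (horiz) {
        path <- cbind(tpos * fy + amp * sin(2 * pi * s + phase), s * fx,
                      zpos + 0.15 * amp * cos(2 * pi * s + phase))
      } else {
        path <- cbind(s * fy, tpos * fx + amp * sin(2 * pi * s + phase),
                      zpos + 0.15 * amp * cos(2 * pi * s + phase))
      }
      vessels[[v]] <- list(path = path, radius = r)
    }
  }

  scene <- structure(
    list(params = params, cells = cells, vessels = vessels, rng_seed = seed),
    class = "synthetic_scene"
  )
  voxelize_scene(scene)
}

# stamp an ellipsoid job list into an integer array
stamp_into <- function(arr, g, jobs, only_empty = TRUE) {
  cpp_stamp(arr, g$ny, g$nx, g$nz, c(g$dy, g$dx, g$dz), jobs, only_empty)
}

# ball sequence along a path at <= half-radius spacing
path_balls <- function(path, radius, label) {
  segs <- diff(path)
  lens <- sqrt(rowSums(segs^2))
  pts <- list(path[1, , drop = FALSE])
  spacing <- max(min(0.5 * radius, 0.4), 0.15)
  for (s in seq_len(nrow(segs))) {
    if (lens[s] < 1e-9) next
    k <- max(1L, ceiling(lens[s] / spacing))
    tt <- seq_len(k) / k
    pts[[length(pts) + 1]] <-
      sweep(outer(tt, segs[s, ]), 2, path[s, ], "+")
  }
  pts <- do.call(rbind, pts)
  cbind(pts, radius, radius, radius, label)
}

voxelize_scene <- function(scene) {
  g <- scene$params$geometry
  labels <- integer(g$ny * g$nx * g$nz)

  # cells first, ascending index: residual collisions go to the lower index
  for (cell in scene$cells) {
    jobs <- rbind(
      c(cell$centroid, cell$soma_radii, cell$id),
      do.call(rbind, lapply(cell$processes, function(p) {
        path_balls(p$path, p$radius, cell$id)
      }))
    )
    labels <- stamp_into(labels, g, jobs, only_empty = TRUE)
  }

  vessel <- integer(g$ny * g$nx * g$nz)
  if (length(scene$vessels) > 0) {
    vjobs <- do.call(rbind, lapply(seq_along(scene$vessels), function(v) {
      path_balls(scene$vessels[[v]]$path, scene$vessels[[v]]$radius, v)
    }))
    vessel <- stamp_into(vessel, g, vjobs, only_empty = TRUE)
    vessel[labels > 0L] <- 0L  # cells own contested voxels
  }

  cd68 <- integer(g$ny * g$nx * g$nz)
  pj <- do.call(rbind, lapply(scene$cells, function(cell) {
    if (is.null(cell$puncta)) return(NULL)
    cbind(cell$puncta[, 1:3, drop = FALSE],
          cell$puncta[, 4], cell$puncta[, 4], cell$puncta[, 4], cell$id)
  }))
  if (!is.null(pj) && nrow(pj) > 0) {
    cd68 <- stamp_into(cd68, g, pj, only_empty = TRUE)
    cd68[cd68 != labels] <- 0L  # puncta live inside their own cell only
  }

  dim(labels) <- c(g$ny, g$nx, g$nz)
  dim(vessel) <- c(g$ny, g$nx, g$nz)
  dim(cd68) <- c(g$ny, g$nx, g$nz)
  sp <- geom_spacing(g)
  attr(labels, "spacing") <- sp
  attr(vessel, "spacing") <- sp
  attr(cd68, "spacing") <- sp

  vv <- voxel_volume_um3(g)
  ids <- seq_along(scene$cells)
  counts <- tabulate(labels[labels > 0L], nbins = max(length(ids), 1L))
  cd68_counts <- tabulate(cd68[cd68 > 0L], nbins = max(length(ids), 1L))
  truth <- tibble(
    label = ids,
    group = scene$params$group,
    target_volume_um3 = purrr::map_dbl(scene$cells, "target_volume"),
    true_volume_um3 = counts[ids] * vv,
    amoeboid = purrr::map_dbl(scene$cells, "amoeboid"),
    cd68_positive = purrr::map_lgl(scene$cells, "cd68_positive"),
    cd68_true_volume_um3 = cd68_counts[ids] * vv
  )

  scene$labels <- labels
  scene$vessel_mask <- vessel > 0L
  scene$cd68_labels <- cd68
  scene$truth <- truth
  scene
}

#' @export
print.synthetic_scene <- function(x, ...) {
  g <- x$params$geometry
  cat(sprintf(
    "<synthetic_scene> %d cells (%s), %d vessels in %d x %d x %d voxels; seed %d\n",
    length(x$cells), x$params$group, length(x$vessels),
    g$ny, g$nx, g$nz, x$rng_seed))
  if (nrow(x$truth) > 0) {
    cat(sprintf("  true volume: mean %.0f um^3, CD68+ %d/%d\n",
                mean(x$truth$true_volume_um3), sum(x$truth$cd68_positive),
                nrow(x$truth)))
  }
  invisible(x)
}

#' Render a synthetic scene into a noisy two-channel stack
#'
#' Channel 1 (IBA-1 analogue) contains the cells and, when vessel bleed is
#' enabled, the vessels; channel 2 (CD68 analogue) contains the puncta.
#' The ideal voxelization is blurred by a separable Gaussian PSF, then
#' Poisson shot noise (at `photon_scale` photons per intensity unit) and
#' Gaussian read noise are added. Ground-truth labels are the un-blurred
#' voxelized objects carried by the scene.
#'
#' @param scene A [generate_scene()] result.
#' @return A list: `stack` (an [mg_stack()] with channels `iba1`, `cd68`),
#'   `labels`, `vessel_mask`, `cd68_labels` (ground truth, copied from the
#'   scene), and `truth`.
#' @export
render_stack <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  with_seed(scene$rng_seed + 1000000L, render_stack_impl(scene))
}

render_stack_impl <- function(scene) {
  p <- scene$params
  g <- p$geometry
  sp <- geom_spacing(g)
  inten <- p$intensity

  # per-cell brightness variation
  gain <- runif(max(length(scene$cells), 1L), 0.8, 1.2)
  lab <- scene$labels
  ch1 <- array(inten$background, dim(lab))
  fg <- lab > 0L
  ch1[fg] <- inten$background + inten$cell * gain[lab[fg]]
  if (p$vessel_bleed) {
    ch1[scene$vessel_mask] <- inten$background + inten$vessel
  }
  ch2 <- array(inten$cd68_background, dim(lab))
  ch2[scene$cd68_labels > 0L] <- inten$cd68_background + inten$puncta

  psf_vox <- c(p$psf_sigma_um[["y"]] / sp[["y"]],
               p$psf_sigma_um[["x"]] / sp[["x"]],
               p$psf_sigma_um[["z"]] / sp[["z"]])
  blur <- function(a) {
    if (all(psf_vox <= 0)) return(a)
    out <- cpp_gauss3(as.numeric(a), g$ny, g$nx, g$nz, psf_vox, c(0L, 0L, 0L))
    dim(out) <- dim(a)
    out
  }
  noisify <- function(a) {
    v <- as.numeric(a)
    if (p$photon_scale > 0) {
      v <- rpois(length(v), pmax(v, 0) * p$photon_scale) / p$photon_scale
    }
    if (p$read_noise_sd > 0) {
      v <- v + rnorm(length(v), sd = p$read_noise_sd)
    }
    dim(v) <- dim(a)
    v
  }
  ch1 <- noisify(blur(ch1))
  ch2 <- noisify(blur(ch2))

  stack <- mg_stack(array(c(ch1, ch2), c(dim(lab), 2L)), sp,
                    channels = c("iba1", "cd68"))
  list(stack = stack, labels = scene$labels,
       vessel_mask = scene$vessel_mask, cd68_labels = scene$cd68_labels,
       truth = scene$truth)
}

#' Voxelize spheres into a logical mask
#'
#' Utility used in examples and validation: voxelizes balls by the
#' voxel-centre-inside rule on the given geometry.
#'
#' @param geometry An [acquisition_geometry()].
#' @param centers Matrix with columns `(y, x, z)` in um.
#' @param radii Radius (um), recycled over rows.
#' @return Logical array `[y, x, z]` with a `spacing` attribute.
#' @export
rasterize_balls <- function(geometry, centers, radii) {
  stopifnot(inherits(geometry, "acq_geometry"))
  centers <- matrix(centers, ncol = 3)
  radii <- rep_len(radii, nrow(centers))
  jobs <- cbind(centers, radii, radii, radii, 1)
  arr <- stamp_into(integer(geometry$ny * geometry$nx * geometry$nz),
                    geometry, jobs, only_empty = FALSE)
  dim(arr) <- c(geometry$ny, geometry$nx, geometry$nz)
  out <- arr > 0L
  attr(out, "spacing") <- geom_spacing(geometry)
  out
}
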