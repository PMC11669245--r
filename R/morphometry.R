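#' 3D metrics of one ROI: volume, convex hull volume, solidity
#'
#' Volume is voxel count times physical voxel volume. The convex hull is
#' taken over the ROI's voxel CORNER points (8 per voxel, physical
#' coordinates), so convex digitized solids score solidity exactly 1 and
#' solidity is guaranteed to lie in (0, 1].
#'
#' @param voxels Integer matrix of 1-based voxel indices, columns `(y, x, z)`.
#' @param spacing Voxel spacing `(y, x, z)` in um.
#' @return List: `volume_um3`, `hull_volume_um3`, `solidity_3d`,
#'   `degenerate` (flag, always `FALSE` for corner clouds of >= 1 voxel).
#' @export
metrics_3d <- function(voxels, spacing) {
  voxels <- matrix(as.numeric(voxels), ncol = 3)
  if (nrow(voxels) == 0) abort("empty ROI")
  vv <- prod(spacing)
  volume <- nrow(voxels) * vv
  corners <- voxel_corner_cloud(voxels, spacing)
  h <- cpp_hull3(corners)
  hull_volume <- h$volume
  degenerate <- isTRUE(h$degenerate)
  if (degenerate || hull_volume < volume) {
    # corner clouds always span 3D; guard against fp slack only
    hull_volume <- max(hull_volume, volume)
  }
  list(volume_um3 = volume, hull_volume_um3 = hull_volume,
       solidity_3d = min(volume / hull_volume, 1), degenerate = degenerate)
}

# corner points (um) of the ROI's surface voxels; interior voxels cannot
# contribute hull vertices, so they are dropped first
voxel_corner_cloud <- function(voxels, spacing) {
  vy <- voxels[, 1]; vx <- voxels[, 2]; vz <- voxels[, 3]
  lo <- c(min(vy), min(vx), min(vz)) - 1L
  dims <- c(max(vy), max(vx), max(vz)) - lo + 1L
  occ <- array(FALSE, dims)
  occ[cbind(vy - lo[1], vx - lo[2], vz - lo[3])] <- TRUE
  inner <- function(a, dy, dx, dz) {
    i <- cbind(vy - lo[1] + dy, vx - lo[2] + dx, vz - lo[3] + dz)
    ok <- i[, 1] >= 1 & i[, 1] <= dims[1] & i[, 2] >= 1 & i[, 2] <= dims[2] &
      i[, 3] >= 1 & i[, 3] <= dims[3]
    res <- logical(nrow(i))
    res[ok] <- a[i[ok, , drop = FALSE]]
    res
  }
  surf <- !(inner(occ, 1, 0, 0) & inner(occ, -1, 0, 0) &
              inner(occ, 0, 1, 0) & inner(occ, 0, -1, 0) &
              inner(occ, 0, 0, 1) & inner(occ, 0, 0, -1))
  vy <- vy[surf]; vx <- vx[surf]; vz <- vz[surf]
  off <- expand.grid(dy = c(-0.5, 0.5), dx = c(-0.5, 0.5), dz = c(-0.5, 0.5))
  pts <- do.call(rbind, lapply(seq_len(nrow(off)), function(k) {
    cbind((vy + off$dy[k]) * spacing[1],
          (vx + off$dx[k]) * spacing[2],
          (vz + off$dz[k]) * spacing[3])
  }))
  unique(pts)
}

#' Z-projection of an ROI
#'
#' Collapses an ROI along the optical axis: pixel `(y, x)` is set iff any
#' voxel `(y, x, z)` belongs to the ROI. Idempotent by construction.
#'
#' @param voxels Integer matrix of voxel indices `(y, x, z)`, or a logical
#'   3D array.
#' @param dim_yx Lateral dimensions `(ny, nx)` (required for the matrix
#'   form).
#' @return Logical matrix `[y, x]`.
#' @export
project_z <- function(voxels, dim_yx = NULL) {
  if (is.array(voxels) && length(dim(voxels)) == 3L) {
    out <- apply(voxels, c(1, 2), any)
    return(out)
  }
  voxels <- matrix(as.integer(voxels), ncol = 3)
  if (is.null(dim_yx)) {
    dim_yx <- c(max(voxels[, 1]), max(voxels[, 2]))
  }
  out <- matrix(FALSE, dim_yx[1], dim_yx[2])
  out[voxels[, 1:2, drop = FALSE]] <- TRUE
  out
}

#' 2D shape metrics of a projected mask
#'
#' Computes the projected-area metric suite: area, perimeter, convex hull
#' area and perimeter, solidity (area / hull area), convexity
#' (hull perimeter / perimeter), circularity (`4*pi*area / perimeter^2`),
#' and the axis lengths of the moment-equivalent ellipse.
#'
#' Perimeter convention: the outer boundary of each 8-connected component is
#' traced over pixel centres, polygonalized into maximal straight runs
#' (points within a strip of width < 1 px), and a `+4 px` Minkowski corner
#' term is added per component. This is exact on axis-aligned rectangles
#' (a 10 x 10 px square has perimeter 40 px) and within ~1% of `2*pi*r` on
#' digitized disks. Hull quantities use the convex hull of pixel corners.
#' Interior holes are not traced: the perimeter is the outer outline, while
#' the area counts true mask pixels only. Multi-component masks are measured
#' as the union (per-component perimeters summed) and flagged.
#'
#' @param mask Logical matrix `[y, x]`.
#' @param pixel_um Lateral pixel size in um.
#' @return List of metrics (um-based units) plus `n_components`.
#' @export
metrics_2d <- function(mask, pixel_um = 1) {
  if (!any(mask)) abort("empty 2D mask")
  d <- dim(mask)
  labs <- cpp_label3(as.logical(mask), d[1], d[2], 1L, 26L)
  ncomp <- attr(labs, "n_labels")
  dim(labs) <- d

  perim_px <- 0
  for (k in seq_len(ncomp)) {
    sub <- labs == k
    perim_px <- perim_px + cpp_trace_perimeter(as.logical(sub), d[1], d[2]) + 4
  }
  perimeter <- perim_px * pixel_um

  npx <- sum(mask)
  area <- npx * pixel_um^2

  # convex hull over pixel corners
  idx <- which(mask, arr.ind = TRUE)
  corners <- rbind(
    cbind(idx[, 1] - 0.5, idx[, 2] - 0.5), cbind(idx[, 1] - 0.5, idx[, 2] + 0.5),
    cbind(idx[, 1] + 0.5, idx[, 2] - 0.5), cbind(idx[, 1] + 0.5, idx[, 2] + 0.5)
  ) * pixel_um
  corners <- unique(corners)
  hull <- grDevices::chull(corners[, 2], corners[, 1])
  hx <- corners[hull, 2]; hy <- corners[hull, 1]
  hull_area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  hull_perimeter <- sum(sqrt(diff(c(hx, hx[1]))^2 + diff(c(hy, hy[1]))^2))

  solidity <- min(area / hull_area, 1)
  convexity <- min(hull_perimeter / perimeter, 1)
  circularity <- 4 * pi * area / perimeter^2

  # moment-equivalent ellipse (pixel-square correction dx^2/12)
  cy <- idx[, 1] * pixel_um; cx <- idx[, 2] * pixel_um
  myy <- mean((cy - mean(cy))^2) + pixel_um^2 / 12
  mxx <- mean((cx - mean(cx))^2) + pixel_um^2 / 12
  mxy <- mean((cy - mean(cy)) * (cx - mean(cx)))
  tr <- (myy + mxx) / 2
  det_ <- sqrt(max(((myy - mxx) / 2)^2 + mxy^2, 0))
  l1 <- tr + det_; l2 <- max(tr - det_, 0)
  major <- 4 * sqrt(l1)
  minor <- 4 * sqrt(l2)

  list(area_um2 = area, perimeter_um = perimeter,
       hull_area_um2 = hull_area, hull_perimeter_um = hull_perimeter,
       solidity_2d = solidity, convexity = convexity,
       circularity = circularity,
       minor_axis_um = minor, major_axis_um = major,
       axis_ratio = if (major > 0) minor / major else 1,
       n_components = ncomp)
}

#' Per-cell morphometry table
#'
#' Runs the full metric suite over every instance of a label volume and
#' returns one tidy row per cell: the 3D metrics (volume, convex hull
#' volume, solidity) and the z-projection 2D metrics (area, perimeter, hull
#' equivalents, solidity, convexity, circularity, axis lengths and ratio).
#'
#' @param labels A `label_volume` (integer array with spacing).
#' @param spacing Voxel spacing if not carried by `labels`.
#' @param stack_id Optional identifier copied into every row.
#' @return A tibble of class `mg_cells`, one row per label.
#' @examples
#' g <- acquisition_geometry(nx = 64, ny = 64, nz = 16, dx = 0.5, dz = 1)
#' ball <- rasterize_balls(g, cbind(16, 16, 8), 5)
#' labels <- array(as.integer(ball), dim(ball))
#' attr(labels, "spacing") <- c(0.5, 0.5, 1)
#' measure_cells(labels)
#' @export
measure_cells <- function(labels, spacing = NULL, stack_id = NA_character_) {
  spacing <- spacing %||% spacing_of(labels)
  n <- max(0L, max(labels))
  if (n == 0L) {
    return(empty_cells_tibble())
  }
  idx_all <- which(labels > 0L)
  coord <- arrayInd(idx_all, dim(labels))
  lab <- labels[idx_all]
  rows <- purrr::map(seq_len(n), function(k) {
    vox <- coord[lab == k, , drop = FALSE]
    if (nrow(vox) == 0) return(NULL)
    m3 <- metrics_3d(vox, spacing)
    proj <- project_z(vox, dim(labels)[1:2])
    m2 <- metrics_2d(proj, spacing[2])
    tibble(
      stack_id = stack_id, label = k, n_voxels = nrow(vox),
      volume_um3 = m3$volume_um3, hull_volume_um3 = m3$hull_volume_um3,
      solidity_3d = m3$solidity_3d,
      area_um2 = m2$area_um2, perimeter_um = m2$perimeter_um,
      hull_area_um2 = m2$hull_area_um2,
      hull_perimeter_um = m2$hull_perimeter_um,
      solidity_2d = m2$solidity_2d, convexity = m2$convexity,
      circularity = m2$circularity,
      minor_axis_um = m2$minor_axis_um, major_axis_um = m2$major_axis_um,
      axis_ratio = m2$axis_ratio,
      n_components_2d = m2$n_components,
      degenerate = m3$degenerate
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("mg_cells", class(out))
  out
}

empty_cells_tibble <- function() {
  out <- tibble(
    stack_id = character(0), label = integer(0), n_voxels = integer(0),
    volume_um3 = numeric(0), hull_volume_um3 = numeric(0),
    solidity_3d = numeric(0), area_um2 = numeric(0),
    perimeter_um = numeric(0), hull_area_um2 = numeric(0),
    hull_perimeter_um = numeric(0), solidity_2d = numeric(0),
    convexity = numeric(0), circularity = numeric(0),
    minor_axis_um = numeric(0), major_axis_um = numeric(0),
    axis_ratio = numeric(0), n_components_2d = integer(0),
    degenerate = logical(0)
  )
  class(out) <- c("mg_cells", class(out))
  out
}

#' Microglia count densities of a stack
#'
#' Both reporting conventions: cells per lateral field area (count/mm^2,
#' the manual-analysis convention) and cells per stack volume (count/mm^3,
#' the machine-analysis convention).
#'
#' @param labels A `label_volume`, or directly a cell count.
#' @param geometry The stack's [acquisition_geometry()].
#' @return A one-row tibble: `n_cells`, `field_area_mm2`, `stack_volume_mm3`,
#'   `density_2d_mm2`, `density_3d_mm3`.
#' @examples
#' g <- acquisition_geometry(nx = 2048, ny = 2048, nz = 40)
#' count_density(50, g)  # ~12249 cells/mm^3
#' @export
count_density <- function(labels, geometry) {
  stopifnot(inherits(geometry, "acq_geometry"))
  n <- if (is.numeric(labels) && length(labels) == 1L) {
    as.integer(labels)
  } else {
    n_labels(labels)
  }
  area_mm2 <- (geometry$nx * geometry$dx / 1000) *
    (geometry$ny * geometry$dy / 1000)
  vol_mm3 <- area_mm2 * geometry$nz * geometry$dz / 1000
  tibble(n_cells = n, field_area_mm2 = area_mm2, stack_volume_mm3 = vol_mm3,
         density_2d_mm2 = n / area_mm2, density_3d_mm3 = n / vol_mm3)
}
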