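#' Acquisition geometry of a confocal z-stack
#'
#' Describes the voxel grid of an acquisition: lateral size in pixels, number
#' of optical slices, and the physical voxel pitch. The reference acquisition
#' regime is a 2048 x 2048 px field scaled to 319.45 x 319.45 um (so
#' dx = dy = 319.45/2048 = 0.156 um/px) with 1 um z-steps; the default here is
#' a desk-scale crop of that regime.
#'
#' @param nx,ny Lateral size in pixels (x = columns, y = rows).
#' @param nz Number of z-slices.
#' @param dx,dy Lateral voxel pitch in um/px; must be equal (square pixels).
#' @param dz Axial pitch in um.
#' @return An `acq_geometry` object (a validated list).
#' @examples
#' g <- acquisition_geometry(nx = 256, ny = 256, nz = 20, dx = 0.5, dz = 1)
#' field_um(g)
#' @export
acquisition_geometry <- function(nx = 512L, ny = 512L, nz = 40L,
                                 dx = 319.45 / 2048, dy = dx, dz = 1) {
  nx <- as.integer(nx); ny <- as.integer(ny); nz <- as.integer(nz)
  if (any(c(nx, ny, nz) <= 0L)) {
    abort("acquisition geometry must have strictly positive dimensions")
  }
  if (any(c(dx, dy, dz) <= 0)) {
    abort("voxel pitches must be strictly positive")
  }
  if (!isTRUE(all.equal(dx, dy))) {
    abort("lateral pixels must be square (dx == dy)")
  }
  structure(
    list(nx = nx, ny = ny, nz = nz, dx = dx, dy = dy, dz = dz),
    class = "acq_geometry"
  )
}

#' @export
print.acq_geometry <- function(x, ...) {
  f <- field_um(x)
  cat(sprintf(
    "<acq_geometry> %d x %d x %d voxels @ %.4g x %.4g x %.4g um  (field %.4g x %.4g x %.4g um)\n",
    x$nx, x$ny, x$nz, x$dx, x$dy, x$dz, f[1], f[2], f[3]
  ))
  invisible(x)
}

#' Physical field size of a geometry
#'
#' @param geometry An [acquisition_geometry()].
#' @return Numeric `(x, y, z)` extent in um.
#' @export
field_um <- function(geometry) {
  stopifnot(inherits(geometry, "acq_geometry"))
  c(x = geometry$nx * geometry$dx,
    y = geometry$ny * geometry$dy,
    z = geometry$nz * geometry$dz)
}

#' @rdname field_um
#' @return `voxel_volume_um3()`: volume of one voxel in um^3.
#' @export
voxel_volume_um3 <- function(geometry) {
  if (inherits(geometry, "acq_geometry")) {
    geometry$dx * geometry$dy * geometry$dz
  } else {
    prod(as.numeric(geometry))
  }
}

spacing_of <- function(x) {
  sp <- attr(x, "spacing")
  if (is.null(sp)) abort("object carries no voxel spacing")
  sp
}

# spacing vector (dy, dx, dz) from a geometry
geom_spacing <- function(geometry) {
  c(y = geometry$dy, x = geometry$dx, z = geometry$dz)
}

#' Multi-channel 3D stack container
#'
#' A thin container for confocal stack data: a numeric array indexed
#' `[y, x, z]` (single channel) or `[y, x, z, channel]`, carrying the voxel
#' spacing in um and channel names. Channel 1 is conventionally the IBA-1
#' (cell) channel and channel 2 the CD68 channel.
#'
#' @param data 3D or 4D numeric array.
#' @param spacing Named numeric `(y, x, z)` voxel pitch in um.
#' @param channels Character vector of channel names.
#' @return An `mg_stack` object.
#' @export
mg_stack <- function(data, spacing, channels = NULL) {
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4L) abort("stack data must be a 3D or 4D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    abort("spacing must be three positive numbers (y, x, z) in um")
  }
  names(spacing) <- c("y", "x", "z")
  nc <- dim(data)[4]
  if (is.null(channels)) {
    channels <- if (nc == 2L) c("iba1", "cd68") else paste0("ch", seq_len(nc))
  }
  stopifnot(length(channels) == nc)
  structure(list(data = data, spacing = spacing, channels = channels),
            class = "mg_stack")
}

#' @export
print.mg_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mg_stack> %d x %d x %d voxels, %d channel(s): %s\n",
              d[1], d[2], d[3], d[4], paste(x$channels, collapse = ", ")))
  cat(sprintf("  spacing %.4g x %.4g x %.4g um (y, x, z)\n",
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Extract one channel of a stack as a 3D array
#'
#' @param stack An [mg_stack()].
#' @param channel Channel name or index.
#' @return 3D array `[y, x, z]` with a `spacing` attribute.
#' @export
stack_channel <- function(stack, channel = 1L) {
  stopifnot(inherits(stack, "mg_stack"))
  if (is.character(channel)) {
    channel <- match(channel, stack$channels)
    if (is.na(channel)) abort("unknown channel name")
  }
  out <- stack$data[, , , channel, drop = FALSE]
  dim(out) <- dim(out)[1:3]
  attr(out, "spacing") <- stack$spacing
  out
}
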