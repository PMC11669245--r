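#' Write a stack to multi-page TIFF with a spacing sidecar
#'
#' Slices are written channel-major (all z of channel 1, then channel 2, ...)
#' as 32-bit float TIFF. Voxel sizes, axis order and channel names go into an
#' OME-style XML description embedded in the TIFF and, redundantly, into a
#' JSON sidecar `<path>.json` so spacing survives TIFF readers that drop the
#' description.
#'
#' @param stack An [mg_stack()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "mg_stack"))
  d <- dim(stack$data)
  rng <- range(stack$data)
  scale <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
  slices <- list()
  for (ch in seq_len(d[4])) {
    for (z in seq_len(d[3])) {
      slices[[length(slices) + 1]] <-
        (stack$data[, , z, ch] - rng[1]) / scale
    }
  }
  meta <- list(
    size_y = d[1], size_x = d[2], size_z = d[3], size_c = d[4],
    physical_size_x = unname(stack$spacing[["x"]]),
    physical_size_y = unname(stack$spacing[["y"]]),
    physical_size_z = unname(stack$spacing[["z"]]),
    unit = "um", axis_order = "CZYX", channels = stack$channels,
    value_offset = rng[1], value_scale = scale
  )
  tiff::writeTIFF(slices, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a stack from TIFF
#'
#' Axes are normalized to the internal `[y, x, z, channel]` layout. Voxel
#' spacing is taken from the JSON sidecar when present, else parsed from an
#' OME-style description, else falls back to `default_spacing` (the
#' reference acquisition pitch, 319.45/2048 um laterally and 1 um axially)
#' with a warning.
#'
#' @param path TIFF file written by [write_stack()] or a plain multi-page
#'   TIFF.
#' @param n_channels Channel count override for plain TIFFs (default 1).
#' @param spacing Spacing override `(y, x, z)` in um.
#' @param default_spacing Fallback spacing when no metadata is found.
#' @return An [mg_stack()].
#' @export
read_stack <- function(path, n_channels = NULL, spacing = NULL,
                       default_spacing = c(319.45 / 2048, 319.45 / 2048, 1)) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  slices <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(slices)) slices <- list(slices)
  meta <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  desc <- attr(slices[[1]], "description")
  offset <- 0; scale <- 1
  if (!is.null(meta)) {
    nc <- meta$size_c
    sp <- c(meta$physical_size_y, meta$physical_size_x, meta$physical_size_z)
    offset <- meta$value_offset %||% 0
    scale <- meta$value_scale %||% 1
    channels <- meta$channels
  } else if (!is.null(desc) && grepl("PhysicalSizeX", desc)) {
    gx <- function(field) {
      as.numeric(sub(paste0(".*", field, "=\"([^\"]+)\".*"), "\\1", desc))
    }
    nc <- gx("SizeC")
    if (is.na(nc)) nc <- 1L
    sp <- c(gx("PhysicalSizeY"), gx("PhysicalSizeX"), gx("PhysicalSizeZ"))
    channels <- NULL
  } else {
    nc <- n_channels %||% 1L
    sp <- NULL
    channels <- NULL
  }
  if (!is.null(n_channels)) nc <- n_channels
  if (!is.null(spacing)) {
    sp <- spacing
  } else if (is.null(sp) || any(is.na(sp))) {
    warn(sprintf(
      "no voxel-size metadata in %s: falling back to %.4g x %.4g x %.4g um",
      path, default_spacing[1], default_spacing[2], default_spacing[3]))
    sp <- default_spacing
  }
  nz <- length(slices) / nc
  if (nz != round(nz)) abort("slice count is not divisible by channel count")
  d1 <- dim(slices[[1]])
  data <- array(NA_real_, c(d1[1], d1[2], nz, nc))
  k <- 1L
  for (ch in seq_len(nc)) {
    for (z in seq_len(nz)) {
      sl <- slices[[k]]
      if (length(dim(sl)) == 3L) sl <- sl[, , 1]
      data[, , z, ch] <- sl * scale + offset
      k <- k + 1L
    }
  }
  mg_stack(data, sp, channels = channels)
}

#' Write / read an instance label volume as 16-bit TIFF
#'
#' @param labels Integer label array (max 65535 labels).
#' @param path Output TIFF; spacing goes to a JSON sidecar.
#' @return `write_labels()`: the path, invisibly; `read_labels()`: a
#'   `label_volume`.
#' @export
write_labels <- function(labels, path) {
  if (max(labels) > 65535L) abort("more than 65535 labels")
  d <- dim(labels)
  slices <- lapply(seq_len(d[3]), function(z) labels[, , z] / 65535)
  tiff::writeTIFF(slices, path, bits.per.sample = 16L, reduce = FALSE)
  sp <- attr(labels, "spacing")
  if (!is.null(sp)) {
    jsonlite::write_json(list(spacing = as.numeric(sp)),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  slices <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(slices)) slices <- list(slices)
  d1 <- dim(slices[[1]])
  out <- array(0L, c(d1[1], d1[2], length(slices)))
  for (z in seq_along(slices)) {
    out[, , z] <- as.integer(round(slices[[z]] * 65535))
  }
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(out, "spacing") <- as.numeric(meta$spacing)
  }
  class(out) <- "label_volume"
  out
}

#' Read / write sparse voxel labels as CSV
#'
#' Plain 4-column CSV `(z, y, x, class)` with 1-based voxel indices.
#'
#' @param labels A [sparse_labels()] tibble.
#' @param path CSV file.
#' @param dim Stack dimensions `(ny, nx, nz)` used for validation on read.
#' @return `write_sparse_labels()`: the path; `read_sparse_labels()`: a
#'   [sparse_labels()] tibble.
#' @export
write_sparse_labels <- function(labels, path) {
  stopifnot(inherits(labels, "sparse_labels"))
  write.csv(labels[, c("z", "y", "x", "class")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sparse_labels
#' @export
read_sparse_labels <- function(path, dim) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  sparse_labels(df[, c("y", "x", "z")], df$class, dim)
}
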