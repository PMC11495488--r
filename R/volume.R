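#' Voxel volume container
#'
#' A 3-D scalar grid with a physical voxel size. Values are stored as an
#' array indexed `[y, x, z]` so that one z-slice is an image matrix
#' (row = y, column = x), the layout of a multi-page TIFF stack. World
#' coordinates are 0-based voxel indices `(x, y, z)` times `voxel_size`.
#'
#' @param values numeric/integer 3-D array, indexed `[y, x, z]`. Binary
#'   volumes hold 0/1; grayscale volumes hold integers in 0..255.
#' @param voxel_size positive scalar, micrometres per voxel edge.
#' @param kind `"binary"` or `"grayscale"`.
#' @return An object of class `trab_volume`.
#' @export
trab_volume <- function(values, voxel_size,
                        kind = c("binary", "grayscale")) {
  kind <- match.arg(kind)
  if (!is.array(values) || length(dim(values)) != 3) {
    stopf("`values` must be a 3-D array")
  }
  if (any(dim(values) < 2)) stopf("grid extents must be >= 2 in every axis")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1 || voxel_size <= 0) {
    stopf("`voxel_size` must be a single positive number (micrometres)")
  }
  if (kind == "binary" && !all(values %in% c(0, 1))) {
    stopf("binary volume must contain only 0 and 1")
  }
  structure(
    list(values = values, voxel_size = voxel_size, kind = kind),
    class = "trab_volume"
  )
}

#' @export
print.trab_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<trab_volume> %s  %d x %d x %d voxels (x, y, z) @ %.4g um, %.1f%% foreground\n",
    x$kind, d[2], d[1], d[3], x$voxel_size,
    100 * mean(x$values > if (x$kind == "binary") 0 else 127)
  ))
  invisible(x)
}

#' @export
dim.trab_volume <- function(x) dim(x$values)

#' Read a multi-page TIFF stack as a voxel volume
#'
#' Pages become z-slices. The voxel size and volume kind are carried in a
#' JSON sidecar written by [write_stack()] (TIFF tags have no standard 3-D
#' spacing); if the sidecar is absent, `voxel_size` must be given.
#'
#' @param path path to a multi-page TIFF file.
#' @param voxel_size fallback voxel size in micrometres when no sidecar
#'   exists.
#' @return A [trab_volume()].
#' @export
read_stack <- function(path, voxel_size = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (file.size(path) == 0) stopf("empty file: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  shapes <- vapply(pages, function(p) paste(dim(p)[1:2], collapse = "x"), "")
  if (length(unique(shapes)) != 1) {
    stopf("ragged TIFF: page %d has shape %s but page 1 has %s",
          which(shapes != shapes[1])[1], shapes[shapes != shapes[1]][1],
          shapes[1])
  }
  if (length(dim(pages[[1]])) > 2) {
    stopf("unsupported bit depth / channels in page 1: expected single-channel")
  }
  side <- sidecar_path(path)
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  vs <- meta$voxel_size %||% voxel_size
  if (is.null(vs)) stopf("no sidecar metadata at %s; supply `voxel_size`", side)
  kind <- meta$kind %||% "grayscale"
  vals <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) vals[, , k] <- pages[[k]]
  vals <- round(vals * 255)
  if (kind == "binary") vals <- (vals > 127) * 1L
  trab_volume(vals, as.numeric(vs), kind = kind)
}

#' Write a voxel volume as a multi-page TIFF stack
#'
#' One 8-bit page per z-slice; binary volumes are written as 0/255. Voxel
#' size and kind go to a JSON sidecar next to the TIFF.
#'
#' @param volume a [trab_volume()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(volume, path) {
  stopifnot(inherits(volume, "trab_volume"))
  nz <- dim(volume$values)[3]
  scale <- if (volume$kind == "binary") 1 else 255
  pages <- lapply(seq_len(nz), function(k) {
    volume$values[, , k, drop = TRUE] / scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  jsonlite::write_json(
    list(voxel_size = volume$voxel_size, kind = volume$kind),
    sidecar_path(path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Mirror a left element onto the right-element convention
#'
#' Reflects the volume across the Y-Z plane (X negated about the grid
#' center). Applying it twice is the identity.
#'
#' @param volume a [trab_volume()].
#' @return The mirrored [trab_volume()].
#' @export
mirror_element <- function(volume) {
  stopifnot(inherits(volume, "trab_volume"))
  volume$values <- volume$values[, rev(seq_len(dim(volume$values)[2])), ,
                                 drop = FALSE]
  volume
}
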