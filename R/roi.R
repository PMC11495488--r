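#' Spherical region of interest
#'
#' @param center 0-based voxel coordinates `(x, y, z)` of the sphere center.
#' @param radius radius in voxels, > 0.
#' @return An object of class `spherical_roi`.
#' @export
spherical_roi <- function(center, radius) {
  if (length(center) != 3 || radius <= 0) {
    stopf("`center` must be (x, y, z) and `radius` > 0")
  }
  structure(list(center = as.numeric(center), radius = radius),
            class = "spherical_roi")
}

#' Interior box of the articular head
#'
#' From the head center, marches a ray along each of the six axis directions
#' until the first cortical voxel; the box face lies just inside that voxel.
#' This operationalizes a box whose sides contact the innermost edges of the
#' cortical bone.
#'
#' @param cortical_mask logical/integer 3-D array (`[y, x, z]` layout),
#'   nonzero at cortical voxels.
#' @param center head center, 0-based voxel coordinates `(x, y, z)`.
#' @return A list with `lo` and `hi`, the inclusive 0-based `(x, y, z)`
#'   corners of the box.
#' @export
interior_box <- function(cortical_mask, center) {
  d <- dim(cortical_mask)
  ny <- d[1]; nx <- d[2]; nz <- d[3]
  c0 <- round(center)
  if (any(c0 < 0) || c0[1] >= nx || c0[2] >= ny || c0[3] >= nz) {
    stopf("head center lies outside the grid")
  }
  if (cortical_mask[c0[2] + 1, c0[1] + 1, c0[3] + 1]) {
    stopf("head center lies inside cortical bone")
  }
  march <- function(step) {
    p <- c0
    repeat {
      p <- p + step
      if (p[1] < 0 || p[1] >= nx || p[2] < 0 || p[2] >= ny ||
          p[3] < 0 || p[3] >= nz) {
        stopf("open cortex: no cortical voxel along axis direction (%d,%d,%d)",
              step[1], step[2], step[3])
      }
      if (cortical_mask[p[2] + 1, p[1] + 1, p[3] + 1]) return(p - step)
    }
  }
  lo <- c(march(c(-1, 0, 0))[1], march(c(0, -1, 0))[2], march(c(0, 0, -1))[3])
  hi <- c(march(c(1, 0, 0))[1], march(c(0, 1, 0))[2], march(c(0, 0, 1))[3])
  if (any(hi < lo)) stopf("interior box is empty")
  list(lo = lo, hi = hi)
}

#' Expand the maximal cortex-free sphere from the interior box center
#'
#' The sphere is centered on the box center with radius one voxel less than
#' the distance to the nearest cortical voxel, capped so it stays inside the
#' grid: the largest spherical ROI that includes trabeculae while excluding
#' all cortical bone.
#'
#' @param box result of [interior_box()].
#' @param cortical_mask as in [interior_box()].
#' @return A [spherical_roi()].
#' @export
expand_sphere <- function(box, cortical_mask) {
  d <- dim(cortical_mask)
  center <- (box$lo + box$hi) / 2
  idx <- which(cortical_mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stopf("cortical mask is empty")
  # arr.ind columns are (y, x, z), 1-based
  dist <- sqrt((idx[, 2] - 1 - center[1])^2 + (idx[, 1] - 1 - center[2])^2 +
                 (idx[, 3] - 1 - center[3])^2)
  radius <- min(dist) - 1
  edge <- min(center[1], d[2] - 1 - center[1],
              center[2], d[1] - 1 - center[2],
              center[3], d[3] - 1 - center[3])
  radius <- min(radius, edge)
  if (radius < 3) {
    stopf("ROI radius %.1f voxels is too small to contain trabeculae", radius)
  }
  spherical_roi(center, radius)
}

#' Otsu threshold of an intensity sample
#'
#' Exhaustive maximization of the between-class variance over the histogram
#' of the supplied intensities; ties are broken by the midpoint of the
#' maximizing threshold range. Voxels with intensity strictly greater than
#' the returned threshold are foreground.
#'
#' @param values numeric vector of intensities (e.g. the voxels inside an
#'   ROI).
#' @return The threshold intensity.
#' @export
otsu_threshold <- function(values) {
  v <- round(as.numeric(values))
  lv <- sort(unique(v))
  if (length(lv) < 2) stopf("constant image: Otsu threshold is undefined")
  counts <- tabulate(match(v, lv))
  n <- length(v)
  # candidate thresholds: all levels except the last (foreground nonempty)
  w0 <- cumsum(counts)[-length(lv)]
  s0 <- cumsum(counts * lv)[-length(lv)]
  w1 <- n - w0
  mu0 <- s0 / w0
  mu1 <- (sum(counts * lv) - s0) / w1
  bcv <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
  # any real threshold in [lv[i], lv[i+1]) yields the same partition as
  # cutting at level i; report the midpoint of the full maximizing range
  best <- which(bcv >= max(bcv) - 1e-12)
  (lv[min(best)] + lv[max(best) + 1]) / 2
}

#' Segment a spherical ROI by Otsu thresholding
#'
#' @param volume a grayscale or binary [trab_volume()].
#' @param roi a [spherical_roi()].
#' @return An object of class `segmented_roi`: the `roi`, logical
#'   `foreground` and `background` arrays partitioning the sphere interior,
#'   the `otsu_threshold` used (NA for already-binary input), and the
#'   `voxel_size`.
#' @export
segment_roi <- function(volume, roi) {
  stopifnot(inherits(volume, "trab_volume"), inherits(roi, "spherical_roi"))
  d <- dim(volume$values)
  sph <- sphere_mask(d, roi$center, roi$radius)
  if (!any(sph)) stopf("empty ROI")
  if (volume$kind == "binary") {
    fg <- sph & volume$values > 0
    thr <- NA_real_
  } else {
    thr <- otsu_threshold(volume$values[sph])
    fg <- sph & volume$values > thr
  }
  structure(
    list(roi = roi, foreground = fg, background = sph & !fg,
         otsu_threshold = thr, voxel_size = volume$voxel_size),
    class = "segmented_roi"
  )
}

#' Purify a binary mask
#'
#' Keeps only the largest foreground connected component (26-connectivity)
#' and fills background cavities (6-connectivity) that do not reach the
#' array boundary — removing free-floating particles and enclosed voids
#' before morphometry. Idempotent.
#'
#' @param mask logical/integer 3-D array.
#' @return A logical array of the same shape.
#' @export
purify <- function(mask) {
  d <- dim(mask)
  m <- as.integer(mask != 0)
  if (sum(m) == 0) stopf("empty foreground: nothing to purify")
  dim_yxz <- d
  lab <- cpp_label_components(m, dim_yxz, 26L)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  out <- array(lab == keep, dim = d)
  # fill enclosed background cavities (6-connected background components
  # that never touch the array boundary)
  bg <- as.integer(!out)
  blab <- array(cpp_label_components(bg, dim_yxz, 6L), dim = d)
  boundary_labels <- unique(c(
    blab[1, , ], blab[d[1], , ], blab[, 1, ], blab[, d[2], ],
    blab[, , 1], blab[, , d[3]]
  ))
  boundary_labels <- boundary_labels[boundary_labels > 0]
  out[blab > 0 & !(blab %in% boundary_labels)] <- TRUE
  out
}
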