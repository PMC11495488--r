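#' Anatomical landmark set for standardized orientation
#'
#' Five landmarks, in 0-based voxel coordinates `(x, y, z)`: the midpoints of
#' the proximal and distal metaphyses, the two lateralmost points where the
#' articular head contacts the anatomical neck, and one point on the
#' articular surface.
#'
#' @param proximal,distal metaphysis midpoints (length-3 numeric).
#' @param lateral_a,lateral_b lateral head-neck contact points.
#' @param articular a point on the articular surface.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(proximal, distal, lateral_a, lateral_b, articular) {
  pts <- list(proximal = proximal, distal = distal, lateral_a = lateral_a,
              lateral_b = lateral_b, articular = articular)
  for (nm in names(pts)) {
    if (!is.numeric(pts[[nm]]) || length(pts[[nm]]) != 3) {
      stopf("landmark `%s` must be a length-3 numeric vector", nm)
    }
  }
  axis <- proximal - distal
  if (sqrt(sum(axis^2)) < 1e-9) {
    stopf("proximal and distal metaphysis midpoints coincide")
  }
  chord <- lateral_a - lateral_b
  zhat <- axis / sqrt(sum(axis^2))
  perp <- chord - sum(chord * zhat) * zhat
  if (sqrt(sum(perp^2)) < 1e-9) {
    stopf("lateral contact chord is collinear with the metaphysis axis")
  }
  structure(pts, class = "landmark_set")
}

landmark_matrix <- function(lm) {
  do.call(rbind, lapply(unclass(lm), as.numeric))
}

#' Rigid transform
#'
#' @param rotation 3x3 orthonormal matrix (det +1, or -1 only for mirrors).
#' @param translation length-3 numeric.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    stopf("rotation must be orthonormal")
  }
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#'
#' @param points an n x 3 matrix or length-3 vector of `(x, y, z)` points.
#' @param transform a [rigid_transform()].
#' @return Transformed points, same shape as the input.
#' @export
transform_points <- function(points, transform) {
  v <- is.null(dim(points))
  p <- if (v) matrix(points, 1, 3) else as.matrix(points)
  out <- p %*% t(transform$rotation) +
    matrix(transform$translation, nrow(p), 3, byrow = TRUE)
  if (v) drop(out) else out
}

#' Standardized-orientation transform from landmarks
#'
#' Returns the proper rigid transform that puts the bone in the uniform
#' comparison frame: the metaphysis-midpoint axis along +Z (proximal up),
#' the lateral-contact chord (orthogonalized against Z) along the Y axis,
#' with the X sign chosen so the articular surface points towards -X.
#' Rotation is about the landmark centroid, so already-oriented landmarks
#' yield the identity.
#'
#' @param landmarks a [landmark_set()].
#' @return A [rigid_transform()] with `det(rotation) = +1`.
#' @export
orientation_transform <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  zhat <- landmarks$proximal - landmarks$distal
  zhat <- zhat / sqrt(sum(zhat^2))
  chord <- landmarks$lateral_a - landmarks$lateral_b
  yhat <- chord - sum(chord * zhat) * zhat
  yhat <- yhat / sqrt(sum(yhat^2))
  xhat <- c(yhat[2] * zhat[3] - yhat[3] * zhat[2],
            yhat[3] * zhat[1] - yhat[1] * zhat[3],
            yhat[1] * zhat[2] - yhat[2] * zhat[1])
  rot <- rbind(xhat, yhat, zhat)
  dimnames(rot) <- NULL
  # head reference: midpoint of the lateral contacts; the articular surface
  # must end up on its -X side
  head_ref <- (landmarks$lateral_a + landmarks$lateral_b) / 2
  art_local <- rot %*% (landmarks$articular - head_ref)
  if (art_local[1] > 0) {
    rot[1, ] <- -rot[1, ]
    rot[2, ] <- -rot[2, ]
  }
  ctr <- colMeans(landmark_matrix(landmarks))
  rigid_transform(rot, as.numeric(ctr - rot %*% ctr))
}

#' Resample a volume under a rigid transform
#'
#' The output grid is the tight axis-aligned bounding box of the transformed
#' input corners plus a 2-voxel pad. Binary volumes must use
#' nearest-neighbour interpolation.
#'
#' @param volume a [trab_volume()].
#' @param transform a [rigid_transform()].
#' @param interpolation `"nearest"` or `"trilinear"`.
#' @param output_grid `"pad"` (default): the tight bounding box of the
#'   transformed input grid plus a 2-voxel pad; `"same"`: resample onto the
#'   input grid.
#' @return A [trab_volume()] on the new grid. The world offset of the output
#'   grid origin is kept in the `"offset"` attribute (so landmark positions
#'   in the output frame are `transform_points(p, transform) - offset`).
#' @export
apply_transform <- function(volume, transform,
                            interpolation = c("nearest", "trilinear"),
                            output_grid = c("pad", "same")) {
  stopifnot(inherits(volume, "trab_volume"),
            inherits(transform, "rigid_transform"))
  interpolation <- match.arg(interpolation)
  output_grid <- match.arg(output_grid)
  if (volume$kind == "binary" && interpolation == "trilinear") {
    stopf("trilinear interpolation is not valid for binary volumes")
  }
  d <- dim(volume$values)
  ny <- d[1]; nx <- d[2]; nz <- d[3]
  if (output_grid == "pad") {
    corners <- as.matrix(expand.grid(x = c(0, nx - 1), y = c(0, ny - 1),
                                     z = c(0, nz - 1)))
    tc <- transform_points(corners, transform)
    lo <- floor(apply(tc, 2, min)) - 2
    hi <- ceiling(apply(tc, 2, max)) + 2
  } else {
    lo <- c(0, 0, 0)
    hi <- c(nx - 1, ny - 1, nz - 1)
  }
  odim <- c(hi[2] - lo[2] + 1, hi[1] - lo[1] + 1, hi[3] - lo[3] + 1)
  # inverse-map every output voxel center into the input grid
  gx <- lo[1] + (seq_len(odim[2]) - 1)
  gy <- lo[2] + (seq_len(odim[1]) - 1)
  gz <- lo[3] + (seq_len(odim[3]) - 1)
  pts <- cbind(
    rep(rep(gx, each = odim[1]), times = odim[3]),
    rep(gy, times = odim[2] * odim[3]),
    rep(gz, each = odim[1] * odim[2])
  )
  rinv <- t(transform$rotation)
  src <- (pts - matrix(transform$translation, nrow(pts), 3, byrow = TRUE)) %*%
    t(rinv)
  out <- numeric(nrow(src))
  if (interpolation == "nearest") {
    ix <- round(src[, 1]); iy <- round(src[, 2]); iz <- round(src[, 3])
    ok <- ix >= 0 & ix < nx & iy >= 0 & iy < ny & iz >= 0 & iz < nz
    out[ok] <- volume$values[cbind(iy[ok] + 1, ix[ok] + 1, iz[ok] + 1)]
  } else {
    fx <- floor(src[, 1]); fy <- floor(src[, 2]); fz <- floor(src[, 3])
    wx <- src[, 1] - fx; wy <- src[, 2] - fy; wz <- src[, 3] - fz
    ok <- fx >= 0 & fx + 1 < nx & fy >= 0 & fy + 1 < ny & fz >= 0 & fz + 1 < nz
    acc <- numeric(sum(ok))
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      w <- (if (cx) wx[ok] else 1 - wx[ok]) *
        (if (cy) wy[ok] else 1 - wy[ok]) *
        (if (cz) wz[ok] else 1 - wz[ok])
      acc <- acc + w * volume$values[cbind(fy[ok] + cy + 1, fx[ok] + cx + 1,
                                           fz[ok] + cz + 1)]
    }
    out[ok] <- acc
  }
  vals <- array(out, dim = odim)
  if (volume$kind == "binary") vals <- (vals > 0.5) * 1L else vals <- round(vals)
  res <- trab_volume(vals, volume$voxel_size, kind = volume$kind)
  attr(res, "offset") <- as.numeric(lo)
  res
}
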