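#' Bone volume fraction of a segmented ROI
#'
#' Foreground voxel count divided by the total voxel count inside the
#' sphere.
#'
#' @param segmented a [segment_roi()] result.
#' @return BV/TV as a fraction in `[0, 1]`.
#' @export
bone_volume_fraction <- function(segmented) {
  stopifnot(inherits(segmented, "segmented_roi"))
  total <- sum(segmented$foreground) + sum(segmented$background)
  if (total == 0) stopf("empty ROI")
  sum(segmented$foreground) / total
}

#' Mean-intercept-length fabric tensor
#'
#' For each of `n_directions` quasi-uniform hemisphere directions (a
#' golden-spiral lattice given a seeded random rotation), casts a grid of
#' parallel test lines through the spherical ROI and measures the mean
#' intercept length `MIL(w) = L(w) * BV/TV / C(w)`, where `L` is the total
#' in-sphere line length and `C` the number of marrow-to-bone crossings.
#' The quadratic form `1/MIL(n)^2 = n' M n` is then fitted by least squares;
#' the fabric ellipsoid radii are the reciprocal square roots of the
#' eigenvalues of `M`.
#'
#' @param segmented a [segment_roi()] result.
#' @param n_directions number of test directions (>= 64).
#' @param line_spacing spacing of parallel lines in voxels.
#' @param seed integer seed for the direction-lattice rotation.
#' @param step sampling step along each line, voxels.
#' @return An object of class `fabric_tensor`: matrix `M`, `radii`
#'   (r1 >= r2 >= r3), `axes` (columns e1, e2, e3, unit vectors),
#'   `n_directions`, `seed`, and the per-direction `mil` table.
#' @export
mil_fabric <- function(segmented, n_directions = 512, line_spacing = 2,
                       seed = 1, step = 0.5) {
  stopifnot(inherits(segmented, "segmented_roi"))
  if (n_directions < 64) stopf("`n_directions` must be >= 64")
  nfg <- sum(segmented$foreground)
  nbg <- sum(segmented$background)
  if (nfg == 0 || nbg == 0) {
    stopf("MIL needs both bone and marrow phases inside the ROI")
  }
  bvtv <- nfg / (nfg + nbg)
  dirs <- hemisphere_directions(n_directions, seed = seed)
  d <- dim(segmented$foreground)
  trace <- cpp_mil_trace(as.integer(segmented$foreground), d,
                         segmented$roi$center, segmented$roi$radius,
                         dirs, line_spacing, step)
  if (any(trace[, 2] == 0)) {
    stopf(paste0("direction with zero phase crossings: ",
                 "enlarge the ROI or coarsen `line_spacing`"))
  }
  mil <- trace[, 1] * bvtv / trace[, 2]
  x <- cbind(dirs[, 1]^2, dirs[, 2]^2, dirs[, 3]^2,
             2 * dirs[, 1] * dirs[, 2], 2 * dirs[, 1] * dirs[, 3],
             2 * dirs[, 2] * dirs[, 3])
  beta <- stats::lm.fit(x, 1 / mil^2)$coefficients
  m <- matrix(c(beta[1], beta[4], beta[5],
                beta[4], beta[2], beta[6],
                beta[5], beta[6], beta[3]), 3, 3)
  eig <- eigen(m, symmetric = TRUE)
  if (any(eig$values <= 0)) {
    stopf("fabric fit is not positive definite; increase `n_directions`")
  }
  radii <- 1 / sqrt(eig$values)   # eigen() sorts values decreasing,
  ord <- order(radii, decreasing = TRUE)  # so radii come out increasing
  structure(
    list(M = m, radii = radii[ord], axes = eig$vectors[, ord, drop = FALSE],
         n_directions = n_directions, seed = seed,
         mil = tibble::tibble(x = dirs[, 1], y = dirs[, 2], z = dirs[, 3],
                              length = trace[, 1], crossings = trace[, 2],
                              mil = mil)),
    class = "fabric_tensor"
  )
}

#' Degree of anisotropy
#'
#' `DA = 1 - r3/r1` from the fabric ellipsoid radii: 0 for an isotropic
#' lattice, approaching 1 for fully aligned struts.
#'
#' @param fabric a [mil_fabric()] result.
#' @return DA in `[0, 1)`.
#' @export
degree_of_anisotropy <- function(fabric) {
  stopifnot(inherits(fabric, "fabric_tensor"))
  1 - fabric$radii[3] / fabric$radii[1]
}

#' Model-independent local thickness
#'
#' Hildebrand-Ruegsegger local thickness: Euclidean distance transform,
#' distance ridge, then sphere painting; the thickness at a voxel is the
#' diameter of the largest inscribed sphere containing it.
#'
#' @param mask logical/integer 3-D array of the phase to measure.
#' @param voxel_size micrometres per voxel edge.
#' @param restrict optional logical array; the mean is taken over
#'   `mask & restrict` (e.g. the ROI sphere).
#' @return A list with `map` (thickness in voxels, diameter) and `mean_mm`.
#' @export
local_thickness <- function(mask, voxel_size, restrict = NULL) {
  d <- dim(mask)
  m <- as.integer(mask != 0)
  if (sum(m) == 0) stopf("empty mask: local thickness is undefined")
  thick <- array(cpp_local_thickness(m, d), dim = d)
  sel <- if (is.null(restrict)) mask != 0 else (mask != 0) & restrict
  list(map = thick, mean_mm = mean(thick[sel]) * voxel_size / 1000)
}

#' Trabecular number
#'
#' `plate_model`: `TbN = (BV/TV) / TbTh`. `intercept`: the mean over MIL
#' test directions of crossings per unit line length. Units: per mm.
#'
#' @param segmented a [segment_roi()] result.
#' @param method `"plate_model"` or `"intercept"`.
#' @param bvtv,tbth_mm precomputed values for the plate model (computed if
#'   missing).
#' @param fabric a [mil_fabric()] result to reuse for the intercept method
#'   (computed with defaults if missing).
#' @return TbN in 1/mm.
#' @export
trabecular_number <- function(segmented, method = c("plate_model", "intercept"),
                              bvtv = NULL, tbth_mm = NULL, fabric = NULL) {
  method <- match.arg(method)
  if (method == "plate_model") {
    if (is.null(bvtv)) bvtv <- bone_volume_fraction(segmented)
    if (is.null(tbth_mm)) {
      sph <- segmented$foreground | segmented$background
      tbth_mm <- local_thickness(segmented$foreground, segmented$voxel_size,
                                 restrict = sph)$mean_mm
    }
    if (tbth_mm <= 0) stopf("TbTh must be positive for the plate model")
    bvtv / tbth_mm
  } else {
    if (is.null(fabric)) fabric <- mil_fabric(segmented)
    len_mm <- fabric$mil$length * segmented$voxel_size / 1000
    mean(fabric$mil$crossings / len_mm)
  }
}

#' Convert a fabric eigenvector to azimuth and plunge
#'
#' The orientation is axial (sign-free); the representative with a
#' non-negative Z component is used. Plunge is the angle between the axis
#' and the X-Y plane (degrees, `[0, 90]`); azimuth is measured from +X
#' towards +Y (degrees, `[0, 360)`). A vertical axis returns azimuth 0 by
#' convention.
#'
#' @param e1 unit 3-vector (x, y, z).
#' @return Named numeric vector `c(azimuth, plunge)` in degrees.
#' @export
eigenvector_to_azimuth_plunge <- function(e1) {
  n <- sqrt(sum(e1^2))
  if (n < 1e-12) stopf("zero vector has no orientation")
  v <- e1 / n
  if (v[3] < 0 || (v[3] == 0 && (v[1] < 0 || (v[1] == 0 && v[2] < 0)))) {
    v <- -v
  }
  plunge <- asin(min(1, v[3])) * 180 / pi
  azimuth <- if (abs(plunge - 90) < 1e-9) 0 else {
    (atan2(v[2], v[1]) * 180 / pi) %% 360
  }
  c(azimuth = azimuth, plunge = plunge)
}

#' Fold an azimuth onto the quarter-turn scale
#'
#' `||x - 180| - 90|`, mapping antipodal and mirror-image compass angles to
#' one value in `[0, 90]` so that nearby directions with discontinuous raw
#' angles (359 and 1 degrees) pair up; used before PCA and group tests.
#'
#' @param x azimuth in degrees, `[0, 360)`.
#' @return Folded angle in `[0, 90]`.
#' @export
fold_azimuth <- function(x) {
  abs(abs(x - 180) - 90)
}

#' Compute the full trabecular metric vector for a segmented ROI
#'
#' @param segmented a [segment_roi()] result.
#' @param n_directions,line_spacing,seed,step MIL parameters, see
#'   [mil_fabric()].
#' @param tbn_method TbN estimator, see [trabecular_number()].
#' @return A one-row tibble: `bvtv`, `da`, `tbth`, `tbsp` (mm), `tbn`
#'   (1/mm), `azimuth`, `plunge` (degrees), plus provenance columns
#'   (`n_directions`, `mil_seed`, `tbn_method`, `otsu_threshold`,
#'   `roi_radius`).
#' @export
compute_all_metrics <- function(segmented, n_directions = 512,
                                line_spacing = 2, seed = 1, step = 0.5,
                                tbn_method = "plate_model") {
  stopifnot(inherits(segmented, "segmented_roi"))
  bvtv <- bone_volume_fraction(segmented)
  fab <- mil_fabric(segmented, n_directions = n_directions,
                    line_spacing = line_spacing, seed = seed, step = step)
  da <- degree_of_anisotropy(fab)
  sph <- segmented$foreground | segmented$background
  tbth <- local_thickness(segmented$foreground, segmented$voxel_size,
                          restrict = sph)$mean_mm
  tbsp <- local_thickness(segmented$background, segmented$voxel_size,
                          restrict = sph)$mean_mm
  tbn <- trabecular_number(segmented, method = tbn_method, bvtv = bvtv,
                           tbth_mm = tbth, fabric = fab)
  ap <- eigenvector_to_azimuth_plunge(fab$axes[, 1])
  tibble::tibble(
    bvtv = bvtv, da = da, tbth = tbth, tbsp = tbsp, tbn = tbn,
    azimuth = ap[["azimuth"]], plunge = ap[["plunge"]],
    n_directions = n_directions, mil_seed = seed, tbn_method = tbn_method,
    otsu_threshold = segmented$otsu_threshold,
    roi_radius = segmented$roi$radius
  )
}
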