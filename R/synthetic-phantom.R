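#' Specification of a rod-lattice trabecular phantom
#'
#' Describes a binary phantom built from cylindrical struts whose axes follow
#' a von Mises-Fisher orientation law: `kappa = 0` gives an isotropic
#' lattice, large `kappa` nearly parallel struts along `mean_axis`.
#'
#' @param shape voxel grid extents, 3 positive integers `(nx, ny, nz)`.
#' @param voxel_size micrometres per voxel edge.
#' @param target_bvtv target bone volume fraction, strictly in (0, 1).
#' @param strut_radius strut radius in voxels, > 0.
#' @param mean_axis unit 3-vector, mean strut direction.
#' @param kappa orientation concentration, >= 0.
#' @param seed integer RNG seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), voxel_size = 30,
                         target_bvtv = 0.3, strut_radius = 3,
                         mean_axis = c(0, 0, 1), kappa = 0, seed = 1) {
  if (length(shape) != 3 || any(shape < 2)) {
    stopf("`shape` must be 3 extents >= 2")
  }
  if (!(target_bvtv > 0 && target_bvtv < 1)) {
    stopf("`target_bvtv` must be strictly between 0 and 1")
  }
  if (strut_radius <= 0) stopf("`strut_radius` must be > 0")
  if (!is_unit_vector(mean_axis)) {
    stopf("`mean_axis` must have unit norm within 1e-9")
  }
  if (kappa < 0) stopf("`kappa` must be >= 0")
  structure(
    list(shape = as.integer(shape), voxel_size = voxel_size,
         target_bvtv = target_bvtv, strut_radius = strut_radius,
         mean_axis = as.numeric(mean_axis), kappa = kappa,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Generate a rod-lattice phantom with known ground truth
#'
#' Rasterizes cylindrical struts until the foreground fraction lands within
#' 0.02 of `target_bvtv`. Strut axes are drawn from a von Mises-Fisher law;
#' anchor points are drawn uniformly on the disk perpendicular to each axis
#' that circumscribes the grid (a uniform line process, so strut density is
#' spatially homogeneous across the grid). Deterministic for a fixed seed.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `volume` (binary [trab_volume()]) and `truth`: the
#'   achieved BV/TV (by direct voxel recount), strut radius, the drawn strut
#'   axes (n x 3), strut count and seed.
#' @export
generate_rod_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nx <- spec$shape[1]; ny <- spec$shape[2]; nz <- spec$shape[3]
  dim_yxz <- c(ny, nx, nz)
  nvox <- prod(dim_yxz)
  vol <- integer(nvox)
  axes <- list()
  ctr <- (c(nx, ny, nz) - 1) / 2
  rcirc <- sqrt(sum(((c(nx, ny, nz) - 1) / 2)^2)) + spec$strut_radius
  with_seed(spec$seed, {
    filled <- 0
    repeat {
      ax <- drop(rvmf(1, spec$mean_axis, spec$kappa))
      basis <- rotation_from_z(ax)
      rho <- rcirc * sqrt(runif(1))
      theta <- runif(1, 0, 2 * pi)
      p0 <- ctr + drop(basis %*% c(rho * cos(theta), rho * sin(theta), 0))
      added <- cpp_raster_cylinder(vol, dim_yxz, p0, ax, spec$strut_radius)
      if (added == 0) next   # line missed the grid entirely
      filled <- filled + added
      axes[[length(axes) + 1]] <- ax
      frac <- filled / nvox
      if (frac > spec$target_bvtv + 0.02) {
        stopf(paste0(
          "target BV/TV %.3f unreachable: one strut of radius %.1f overshot ",
          "to %.3f; reduce strut_radius or enlarge the grid"),
          spec$target_bvtv, spec$strut_radius, frac)
      }
      if (frac >= spec$target_bvtv - 0.02) break
      if (length(axes) > 2e5) stopf("strut budget exhausted before target BV/TV")
    }
  })
  values <- array(vol, dim = dim_yxz)
  achieved <- sum(values) / nvox
  list(
    volume = trab_volume(values, spec$voxel_size, kind = "binary"),
    truth = list(
      achieved_bvtv = achieved,
      strut_radius = spec$strut_radius,
      axes = do.call(rbind, axes),
      n_struts = length(axes),
      mean_axis = spec$mean_axis,
      kappa = spec$kappa,
      seed = spec$seed
    )
  )
}

#' Specification of a whole-bone mock
#'
#' A sphere-capped vertical shaft with a solid cortical shell, a rod-lattice
#' trabecular interior, and an optional growth-plate slab, plus the five
#' orientation landmarks. Used to exercise the orientation and ROI stages.
#'
#' @param shape voxel grid extents `(nx, ny, nz)`.
#' @param outer_radius articular-head outer radius, voxels.
#' @param cortical_thickness cortical shell thickness, voxels (must be less
#'   than `outer_radius`).
#' @param head_center head center `(x, y, z)`, voxels.
#' @param interior a [phantom_spec()] for the trabecular interior (its
#'   `shape` is ignored; the mock grid is used).
#' @param growth_plate optional `list(z, thickness)`: a solid slab of bone
#'   spanning `[z, z + thickness)` inside the head cavity.
#' @param noise_sd grayscale noise, as a fraction of the bone/background
#'   class separation.
#' @param voxel_size micrometres per voxel edge.
#' @param seed integer RNG seed.
#' @return An object of class `whole_bone_spec`.
#' @export
whole_bone_spec <- function(shape = c(96, 96, 96), outer_radius = 40,
                            cortical_thickness = 5,
                            head_center = c(47, 47, 52),
                            interior = phantom_spec(target_bvtv = 0.3,
                                                    strut_radius = 2.5,
                                                    kappa = 5),
                            growth_plate = NULL, noise_sd = 0,
                            voxel_size = 30, seed = 1) {
  if (cortical_thickness >= outer_radius) {
    stopf("`cortical_thickness` must be smaller than `outer_radius`")
  }
  lms <- rbind(head_center,
               c(head_center[1], head_center[2], 6),
               head_center + c(0, outer_radius, 0),
               head_center - c(0, outer_radius, 0),
               head_center + c(-outer_radius, 0, 0))
  inside <- lms[, 1] >= 0 & lms[, 1] <= shape[1] - 1 &
    lms[, 2] >= 0 & lms[, 2] <= shape[2] - 1 &
    lms[, 3] >= 0 & lms[, 3] <= shape[3] - 1
  if (!all(inside)) stopf("landmark points fall outside the grid")
  if (!is.null(growth_plate)) {
    z0 <- growth_plate$z
    z1 <- growth_plate$z + growth_plate$thickness
    if (z0 < head_center[3] - outer_radius || z1 > head_center[3] + outer_radius) {
      stopf("growth-plate slab lies outside the articular head")
    }
  }
  structure(
    list(shape = as.integer(shape), outer_radius = outer_radius,
         cortical_thickness = cortical_thickness,
         head_center = as.numeric(head_center), interior = interior,
         growth_plate = growth_plate, noise_sd = noise_sd,
         voxel_size = voxel_size, seed = as.integer(seed)),
    class = "whole_bone_spec"
  )
}

#' Generate a whole-bone mock
#'
#' @param spec a [whole_bone_spec()].
#' @return A list with `grayscale` (a [trab_volume()]), `labels` (integer
#'   array: 0 background, 1 trabecular bone, 2 cortical bone), and
#'   `landmarks` (a [landmark_set()] in voxel coordinates).
#' @export
generate_whole_bone <- function(spec) {
  stopifnot(inherits(spec, "whole_bone_spec"))
  nx <- spec$shape[1]; ny <- spec$shape[2]; nz <- spec$shape[3]
  dim_yxz <- c(ny, nx, nz)
  hc <- spec$head_center
  y <- (seq_len(ny) - 1); x <- (seq_len(nx) - 1); z <- (seq_len(nz) - 1)
  # head sphere union a vertical shaft cylinder below the head center
  d2_head <- outer(outer((y - hc[2])^2, (x - hc[1])^2, `+`), (z - hc[3])^2, `+`)
  shaft_r <- 0.7 * spec$outer_radius
  d2_axis <- outer(outer((y - hc[2])^2, (x - hc[1])^2, `+`), 0 * z, `+`)
  # shaft spans a closed bottom (z = 6) up to the head center, so the
  # cortical shell caps the cavity on all six axis directions
  below <- outer(outer(0 * y, 0 * x, `+`),
                 as.numeric(z <= hc[3] & z >= 6), `+`) > 0
  solid <- (d2_head <= spec$outer_radius^2) | (d2_axis <= shaft_r^2 & below)
  # cortical shell: solid voxels within `cortical_thickness` of the outside
  edt <- array(cpp_edt_sq(as.integer(solid), dim_yxz), dim = dim_yxz)
  cortical <- solid & sqrt(edt) <= spec$cortical_thickness
  interior <- solid & !cortical
  ispec <- spec$interior
  ispec$shape <- spec$shape
  ispec$seed <- spec$seed
  rods <- generate_rod_phantom(ispec)$volume$values
  trab <- interior & (rods > 0)
  if (!is.null(spec$growth_plate)) {
    zin <- z >= spec$growth_plate$z &
      z < spec$growth_plate$z + spec$growth_plate$thickness
    slab <- outer(outer(0 * y, 0 * x, `+`), as.numeric(zin), `+`) > 0
    trab <- trab | (interior & slab)
  }
  labels <- array(0L, dim = dim_yxz)
  labels[trab] <- 1L
  labels[cortical] <- 2L
  gray <- array(40, dim = dim_yxz)
  gray[labels > 0] <- 200
  if (spec$noise_sd > 0) {
    gray <- gray + with_seed(spec$seed + 1L,
                             array(rnorm(length(gray), 0, spec$noise_sd * 160),
                                   dim = dim_yxz))
  }
  gray <- array(pmin(255, pmax(0, round(gray))), dim = dim_yxz)
  landmarks <- landmark_set(
    proximal = hc,
    distal = c(hc[1], hc[2], 0),
    lateral_a = hc + c(0, spec$outer_radius, 0),
    lateral_b = hc - c(0, spec$outer_radius, 0),
    articular = hc + c(-spec$outer_radius, 0, 0)
  )
  list(
    grayscale = trab_volume(gray, spec$voxel_size, kind = "grayscale"),
    labels = labels,
    landmarks = landmarks
  )
}
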