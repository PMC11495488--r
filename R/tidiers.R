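#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a scaling regression
#'
#' One row per linear-fit coefficient, with the slope row carrying the 95%
#' CI and the isometric reference.
#'
#' @param x a [scaling_regression()] fit.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.trab_scaling <- function(x, ...) {
  sm <- summary(x$linear_fit)$coefficients
  tibble::tibble(
    term = rownames(sm),
    estimate = sm[, 1],
    std_error = sm[, 2],
    statistic = sm[, 3],
    p_value = sm[, 4],
    conf_low = c(NA, x$slope_ci[[1]]),
    conf_high = c(NA, x$slope_ci[[2]]),
    isometric_reference = c(NA, x$isometric_reference)
  )
}

#' @rdname tidy.trab_scaling
#' @export
glance.trab_scaling <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    chosen_degree = x$chosen_degree,
    cv_mse = x$cv_mse[[paste0("degree_", x$chosen_degree)]],
    slope = x$slope,
    conf_low = x$slope_ci[[1]],
    conf_high = x$slope_ci[[2]],
    isometric_reference = x$isometric_reference,
    isometry_rejected = x$isometry_rejected,
    r_squared = summary(x$linear_fit)$r.squared
  )
}

#' Tidy a fabric tensor
#'
#' One row per principal axis with its ellipsoid radius and orientation.
#'
#' @param x a [mil_fabric()] result.
#' @param ... unused.
#' @return A tibble with columns `axis`, `radius`, `x`, `y`, `z`,
#'   `azimuth`, `plunge`.
#' @export
tidy.fabric_tensor <- function(x, ...) {
  ap <- t(apply(x$axes, 2, eigenvector_to_azimuth_plunge))
  axes <- x$axes
  tibble::tibble(
    axis = paste0("e", 1:3),
    radius = x$radii,
    x = axes[1, ], y = axes[2, ], z = axes[3, ],
    azimuth = ap[, 1], plunge = ap[, 2]
  )
}

#' @rdname tidy.fabric_tensor
#' @export
glance.fabric_tensor <- function(x, ...) {
  tibble::tibble(
    da = degree_of_anisotropy(x),
    r1 = x$radii[1], r2 = x$radii[2], r3 = x$radii[3],
    n_directions = x$n_directions,
    seed = x$seed
  )
}

#' Tidy a PCA of the metric table
#'
#' @param x a [pca_metrics()] result.
#' @param matrix `"loadings"` (default) or `"scores"`.
#' @param ... unused.
#' @return A tibble in long form.
#' @export
tidy.trab_pca <- function(x, matrix = c("loadings", "scores"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "loadings") {
    m <- x$loadings
    tibble::tibble(
      variable = rep(rownames(m), ncol(m)),
      component = rep(colnames(m), each = nrow(m)),
      loading = as.vector(m)
    )
  } else {
    dplyr::mutate(x$scores, row = dplyr::row_number(), .before = 1)
  }
}

#' @rdname tidy.trab_pca
#' @export
glance.trab_pca <- function(x, ...) {
  tibble::tibble(
    component = paste0("PC", seq_along(x$explained_variance)),
    explained_variance = x$explained_variance,
    cumulative = cumsum(x$explained_variance)
  )
}
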