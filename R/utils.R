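#' @importFrom Rcpp sourceCpp
#' @useDynLib trabkit, .registration = TRUE
#' @importFrom rlang .data %||% abort
#' @importFrom stats sd cor var rnorm runif rlnorm setNames
#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a stage-specific 31-bit seed from a global seed and a stage name.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 48271 + h) %% 2147483647L)
}

stopf <- function(fmt, ...) abort(sprintf(fmt, ...))

is_unit_vector <- function(v, tol = 1e-9) {
  length(v) == 3 && abs(sqrt(sum(v^2)) - 1) < tol
}

# Quasi-uniform hemisphere directions (golden-spiral lattice), optionally
# rotated by a seeded random proper rotation. Rows are (x, y, z) unit vectors.
hemisphere_directions <- function(n, seed = NULL) {
  i <- seq_len(n)
  z <- (i - 0.5) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  dirs <- cbind(r * cos(phi), r * sin(phi), z)
  if (!is.null(seed)) {
    rot <- with_seed(seed, random_rotation())
    dirs <- dirs %*% t(rot)
  }
  dirs
}

# Uniform random proper rotation (QR of a Gaussian matrix, det corrected).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Draw n unit vectors from a von Mises-Fisher distribution on the sphere with
# mean direction mu and concentration kappa (kappa = 0: uniform).
rvmf <- function(n, mu, kappa) {
  stopifnot(is_unit_vector(mu, tol = 1e-6))
  if (kappa < 1e-12) {
    v <- matrix(rnorm(3 * n), n, 3)
    return(v / sqrt(rowSums(v^2)))
  }
  u <- runif(n)
  # inverse-CDF sample of the cosine w = cos(angle to mu)
  w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  theta <- runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - w^2))
  local_v <- cbind(s * cos(theta), s * sin(theta), w)
  # rotate the pole (0,0,1) onto mu
  local_v %*% t(rotation_from_z(mu))
}

# Proper rotation taking (0, 0, 1) to the unit vector mu.
rotation_from_z <- function(mu) {
  z <- c(0, 0, 1)
  c_ <- sum(z * mu)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(diag(c(1, -1, -1)))
  v <- c(z[2] * mu[3] - z[3] * mu[2],
         z[3] * mu[1] - z[1] * mu[3],
         z[1] * mu[2] - z[2] * mu[1])
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

# Logical mask of voxels whose centers lie within `radius` of `center`
# (center and radius in 0-based voxel coordinates, array laid out [y, x, z]).
sphere_mask <- function(dim_yxz, center_xyz, radius) {
  ny <- dim_yxz[1]; nx <- dim_yxz[2]; nz <- dim_yxz[3]
  y <- (seq_len(ny) - 1) - center_xyz[2]
  x <- (seq_len(nx) - 1) - center_xyz[1]
  z <- (seq_len(nz) - 1) - center_xyz[3]
  d2 <- outer(outer(y^2, x^2, `+`), z^2, `+`)
  array(d2 <= radius^2, dim = dim_yxz)
}
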