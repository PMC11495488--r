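hollow_cube <- function(n = 50, inner = 30) {
  # cube shell centered in an n^3 grid with an inner cavity of side `inner`
  m <- array(FALSE, c(n, n, n))
  lo <- (n - inner) / 2 + 1
  hi <- lo + inner - 1
  shell_lo <- lo - 3
  shell_hi <- hi + 3
  m[shell_lo:shell_hi, shell_lo:shell_hi, shell_lo:shell_hi] <- TRUE
  m[lo:hi, lo:hi, lo:hi] <- FALSE
  m
}

hollow_sphere <- function(n, r_in, r_out, center = (c(n, n, n) - 1) / 2) {
  outer_m <- trabkit:::sphere_mask(c(n, n, n), center, r_out)
  inner_m <- trabkit:::sphere_mask(c(n, n, n), center, r_in)
  outer_m & !inner_m
}

test_that("interior box contacts the innermost cortical edges", {
  m <- hollow_cube(50, 30)
  ctr <- c(24.5, 24.5, 24.5)
  box <- interior_box(m, ctr)
  expect_true(all(abs((box$hi - box$lo + 1) - 30) <= 1))
  # hollow sphere of inner radius 18: box extent ~ 2r per axis
  s <- hollow_sphere(50, 18, 23)
  box2 <- interior_box(s, c(24.5, 24.5, 24.5))
  expect_true(all(abs((box2$hi - box2$lo + 1) - 36) <= 2))
})

test_that("off-center cavities give asymmetric boxes matching a ray oracle", {
  s <- hollow_sphere(60, 16, 21, center = c(25, 32, 30))
  ctr <- c(25, 32, 30)
  box <- interior_box(s, ctr)
  # independent per-axis scan over the mask
  scan <- function(step) {
    p <- ctr
    repeat {
      p <- p + step
      if (s[p[2] + 1, p[1] + 1, p[3] + 1]) return(p - step)
    }
  }
  expect_equal(box$lo,
               c(scan(c(-1, 0, 0))[1], scan(c(0, -1, 0))[2],
                 scan(c(0, 0, -1))[3]))
  expect_equal(box$hi,
               c(scan(c(1, 0, 0))[1], scan(c(0, 1, 0))[2],
                 scan(c(0, 0, 1))[3]))
})

test_that("open cortex is reported, not silently boxed", {
  m <- hollow_cube(40, 20)
  m[, , 30:40] <- FALSE # remove the +Z face
  expect_error(interior_box(m, c(19.5, 19.5, 19.5)), "open cortex")
})

test_that("the expanded sphere is maximal and cortex-free", {
  s <- hollow_sphere(96, 40, 46)
  box <- interior_box(s, c(47.5, 47.5, 47.5))
  roi <- expand_sphere(box, s)
  expect_gte(roi$radius, 38)
  expect_lte(roi$radius, 40)
  # a cortical voxel planted ~9 voxels off-center (off the axis rays, so
  # the interior box is unchanged) caps the radius
  s2 <- s
  s2[55, 55, 48] <- TRUE # voxel (x = 54, y = 54, z = 47), distance ~9.2
  roi2 <- expand_sphere(interior_box(s2, c(47.5, 47.5, 47.5)), s2)
  expect_lte(roi2$radius, 9)
  # random shells: radius equals brute-force min distance minus 1
  for (seed in 1:3) {
    cfg <- trabkit:::with_seed(seed, {
      list(r_in = runif(1, 10, 14), r_out = runif(1, 16, 19),
           c = runif(3, 19, 21))
    })
    sh <- hollow_sphere(40, cfg$r_in, cfg$r_out, center = cfg$c)
    b <- interior_box(sh, cfg$c)
    roi3 <- expand_sphere(b, sh)
    idx <- which(sh, arr.ind = TRUE)
    ctr <- (b$lo + b$hi) / 2
    brute <- min(sqrt((idx[, 2] - 1 - ctr[1])^2 + (idx[, 1] - 1 - ctr[2])^2 +
                        (idx[, 3] - 1 - ctr[3])^2)) - 1
    expect_equal(roi3$radius, min(brute, 19.5 - max(abs(ctr - 19.5))),
                 tolerance = 1e-9)
  }
  # the ROI sphere never contains a cortical voxel
  sph <- trabkit:::sphere_mask(dim(s), roi$center, roi$radius)
  expect_false(any(sph & s))
})

test_that("tiny cavities are rejected as ROIs", {
  s <- hollow_sphere(20, 3.2, 8)
  expect_error(expand_sphere(interior_box(s, c(9.5, 9.5, 9.5)), s),
               "too small")
})

test_that("Otsu separates a two-value image exactly", {
  v <- c(rep(40, 700), rep(200, 300))
  thr <- otsu_threshold(v)
  expect_gt(thr, 40)
  expect_lt(thr, 200)
  expect_true(all((v > thr) == (v == 200)))
  expect_error(otsu_threshold(rep(7, 100)), "constant")
})

test_that("Otsu matches the exhaustive between-class-variance oracle", {
  for (seed in 1:25) {
    v <- trabkit:::with_seed(seed, {
      n1 <- sample(20:200, 1)
      n2 <- sample(20:200, 1)
      round(c(rnorm(n1, 80, 25), rnorm(n2, 170, 30)))
    })
    expect_equal(otsu_threshold(v), oracle_otsu(v))
  }
})

test_that("noise-free mock segmentation reproduces the generator labels", {
  gen <- generate_whole_bone(whole_bone_spec(noise_sd = 0, seed = 5))
  cort <- gen$labels == 2
  box <- interior_box(cort, gen$landmarks$proximal)
  roi <- expand_sphere(box, cort)
  seg <- segment_roi(gen$grayscale, roi)
  sph <- seg$foreground | seg$background
  expect_true(all(seg$foreground == ((gen$labels == 1) & sph)))
})

test_that("segmentation stays accurate under strong grayscale noise", {
  gen <- generate_whole_bone(whole_bone_spec(noise_sd = 0.2, seed = 6))
  cort <- gen$labels == 2
  roi <- expand_sphere(interior_box(cort, gen$landmarks$proximal), cort)
  seg <- segment_roi(gen$grayscale, roi)
  sph <- seg$foreground | seg$background
  acc <- mean((seg$foreground == ((gen$labels == 1) & sph))[sph])
  expect_gte(acc, 0.99)
})

test_that("purify keeps the largest component and fills cavities", {
  m <- array(FALSE, c(20, 20, 20))
  m[5:15, 5:15, 5:15] <- TRUE   # big block
  m[10, 10, 10] <- FALSE        # enclosed cavity
  m[2, 2, 2] <- TRUE            # floater
  p <- purify(m)
  expect_false(p[2, 2, 2])
  expect_true(p[10, 10, 10])
  expect_true(all(p[5:15, 5:15, 5:15]))
  # idempotent
  expect_identical(purify(p), p)
  expect_error(purify(array(FALSE, c(4, 4, 4))), "empty foreground")
})

test_that("purify matches the flood-fill oracle on random speckle", {
  for (seed in 1:8) {
    m <- trabkit:::with_seed(seed,
                             array(runif(24^3) < 0.22, c(24, 24, 24)))
    if (!any(m)) next
    expect_identical(purify(m), oracle_purify(m))
  }
})
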