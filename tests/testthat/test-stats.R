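test_that("body-mass estimation follows the scaling equation", {
  expect_equal(estimate_log_body_mass(10, c(1, 0)), 1.0)
  expect_equal(estimate_log_body_mass(123, c(0, 0.75)), 0.75)
  expect_equal(specimen_log_body_mass(c(0.6, 0.8)), 0.7)
  expect_error(estimate_log_body_mass(10, NULL), "required configuration")
  expect_error(estimate_log_body_mass(-1, c(1, 0)), "positive")
})

test_that("coefficient of variation matches the hand formula", {
  expect_equal(coefficient_of_variation(c(3, 3, 3)), 0)
  expect_equal(coefficient_of_variation(c(2, 4, 6)), 50)
  expect_error(coefficient_of_variation(5), "at least 2")
  expect_error(coefficient_of_variation(c(-1, 1)), "zero-mean")
})

test_that("simulated group CVs are recovered across replicates", {
  # 2-month humeral DA has CV 22.1; mean recovered CV over many replicate
  # draws of n = 13 stays within 15%
  cvs <- trabkit:::with_seed(77, vapply(1:1000, function(i) {
    coefficient_of_variation(trabkit:::draw_mean_cv(13, 0.19, 22.1))
  }, 0))
  expect_lt(abs(mean(cvs) - 22.1) / 22.1, 0.15)
})

test_that("correlation matrices match hand and residual oracles", {
  x <- c(1, 2, 3, 4)
  res <- correlation_matrix(data.frame(x = x, y = 2 * x))
  expect_equal(res$r["x", "y"], 1)
  res2 <- correlation_matrix(data.frame(x = c(1, 2, 3, 1.5),
                                        y = c(1, 3, 2, 2.2)))
  expect_equal(res2$r, t(res2$r))
  expect_equal(diag(res2$r), c(x = 1, y = 1))
  # hand computation of centered products on a 4-point set
  xs <- c(1, 2, 3, 1.5)
  ys <- c(1, 3, 2, 2.2)
  hand <- sum((xs - mean(xs)) * (ys - mean(ys))) /
    sqrt(sum((xs - mean(xs))^2) * sum((ys - mean(ys))^2))
  expect_equal(res2$r["x", "y"], hand, tolerance = 1e-12)
  # pearson matches the covariance definition
  set.seed(3)
  df <- as.data.frame(matrix(rnorm(60), 20, 3,
                             dimnames = list(NULL, c("a", "b", "c"))))
  pr <- correlation_matrix(df, "pearson")
  expect_equal(pr$r["a", "b"],
               cov(df$a, df$b) / sqrt(var(df$a) * var(df$b)),
               tolerance = 1e-12)
  # partial correlation equals residual-on-residual correlation
  df$c2 <- df$a + df$b + rnorm(20, 0, 0.3)
  pc <- correlation_matrix(df[, c("a", "b", "c2")], "partial")
  ra <- resid(lm(a ~ c2, df))
  rb <- resid(lm(b ~ c2, df))
  expect_equal(pc$r["a", "b"], cor(ra, rb), tolerance = 1e-8)
  expect_lt(pc$r["a", "b"], -0.5) # z = x + y makes x,y|z strongly negative
})

test_that("PCA is exact, ordered, and sign-stable", {
  set.seed(5)
  df <- tibble::tibble(a = rnorm(30), b = rnorm(30, sd = 0.2),
                       c = rnorm(30, sd = 0.1))
  p <- pca_metrics(df, c("a", "b", "c"))
  # reconstruction identity
  rec <- as.matrix(p$scores) %*% t(p$loadings) +
    matrix(p$center, 30, 3, byrow = TRUE)
  expect_equal(unname(rec), unname(as.matrix(df)), tolerance = 1e-9)
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  # variance confined to one column concentrates PC1 there
  df2 <- tibble::tibble(a = rnorm(20), b = rep(1, 20), c = rep(2, 20))
  p2 <- pca_metrics(df2, c("a", "b", "c"))
  expect_equal(p2$explained_variance[1], 1)
  expect_equal(abs(p2$loadings["a", 1]), 1, tolerance = 1e-9)
  # sign convention: dominant loading positive
  expect_gt(p2$loadings["a", 1], 0)
  expect_error(pca_metrics(df2, c("a", "b"), scale = TRUE), "constant column")
  expect_error(pca_metrics(df, c("a", "azimuth")), "folded azimuth")
})

test_that("a strong co-trend earns the largest PC1 loadings", {
  set.seed(8)
  n <- 60
  drive <- rnorm(n)
  df <- tibble::tibble(
    logbm = drive + rnorm(n, 0, 0.3),
    da = drive + rnorm(n, 0, 0.3),
    plunge = drive + rnorm(n, 0, 0.3),
    tbth = rnorm(n), tbsp = rnorm(n), tbn = rnorm(n)
  )
  p <- pca_metrics(df, names(df), scale = TRUE)
  top3 <- names(sort(abs(p$loadings[, 1]), decreasing = TRUE))[1:3]
  expect_setequal(top3, c("logbm", "da", "plunge"))
})

test_that("Kruskal-Wallis reproduces hand values and handles ties", {
  res <- kruskal_wallis(1:9, rep(1:3, each = 3))
  expect_equal(res$statistic, 7.2, tolerance = 1e-12)
  expect_equal(res$df, 2)
  const <- kruskal_wallis(rep(5, 9), rep(1:3, each = 3))
  expect_equal(const$statistic, 0)
  expect_equal(const$p_value, 1)
  expect_error(kruskal_wallis(1:3, rep(1, 3)), "2 nonempty groups")
})

test_that("Kruskal-Wallis and Dunn match brute-force oracles", {
  for (seed in 1:100) {
    sim <- trabkit:::with_seed(seed, {
      g <- rep(1:3, times = sample(3:6, 3, replace = TRUE))
      v <- sample(1:8, length(g), replace = TRUE) # heavy ties
      list(g = g, v = v)
    })
    res <- kruskal_wallis(sim$v, sim$g)
    expect_equal(res$statistic, oracle_kruskal(sim$v, sim$g),
                 tolerance = 1e-10)
    d <- suppressWarnings(dunn_posthoc(sim$v, sim$g))
    for (i in seq_len(nrow(d))) {
      expect_equal(d$z[i],
                   oracle_dunn_z(sim$v, sim$g, d$group1[i], d$group2[i]),
                   tolerance = 1e-10)
    }
  }
})

test_that("Dunn gating, degenerate pairs and adjustment behave", {
  v <- c(1, 2, 3, 1, 2, 3)
  g <- rep(c("a", "b"), each = 3)
  d <- suppressWarnings(dunn_posthoc(v, g))
  expect_equal(d$z, 0)
  expect_equal(d$p_value, 1)
  expect_true(attr(d, "standalone"))
  expect_warning(dunn_posthoc(v, g), "standalone")
  expect_error(dunn_posthoc(v, g, omnibus_p = 0.2), "refused")
  # bonferroni multiplies by the number of pairs, capped at 1
  v2 <- c(1:5, 6:10, 11:15, 16:20, 21:25)
  g2 <- rep(1:5, each = 5)
  d2 <- dunn_posthoc(v2, g2, adjustment = "bonferroni", omnibus_p = 0.001)
  expect_equal(d2$p_adjusted, pmin(1, 10 * d2$p_value))
})

test_that("scaling regression selects the right degree and tests isometry", {
  x <- seq(0, 2, length.out = 40)
  y <- 1 + 2 * x - 0.7 * x^2 # noise-free quadratic
  fit <- scaling_regression(x, y, isometric_reference = 0, k = 10, seed = 1)
  expect_equal(fit$chosen_degree, 2)
  expect_lt(fit$cv_mse[["degree_2"]], 1e-20)
  # slope 1/3 simulation: CI covers 0.33
  sim <- trabkit:::with_seed(2, {
    lx <- runif(50, 0.3, 1.2)
    list(x = lx, y = (1 / 3) * lx + rnorm(50, 0, 0.02))
  })
  fit2 <- scaling_regression(sim$x, sim$y, isometric_reference = 1 / 3,
                             seed = 2)
  expect_lt(fit2$slope_ci[["lower"]], 0.33)
  expect_gt(fit2$slope_ci[["upper"]], 0.33)
  expect_false(fit2$isometry_rejected)
  expect_error(scaling_regression(1:5, 1:5, k = 10), "folds exceed")
})

test_that("the isometry test holds its nominal size under the null", {
  rejections <- trabkit:::with_seed(9, vapply(1:400, function(i) {
    x <- runif(50, 0.3, 1.2)
    y <- rnorm(50, 0, 0.02) # slope exactly 0
    fit <- scaling_regression(x, y, isometric_reference = 0,
                              candidate_degrees = 1, k = 5, seed = i)
    fit$isometry_rejected
  }, TRUE))
  expect_gte(mean(!rejections), 0.90)
})

test_that("equal-area projection maps the reference orientations", {
  expect_equal(stereographic_projection(0, 90), tibble::tibble(px = 0, py = 0))
  p <- stereographic_projection(0, 0)
  expect_equal(p$px, 0)
  expect_equal(p$py, 1)
  # antipodal azimuths at plunge 0 are diametrically opposite on the circle
  q <- stereographic_projection(c(30, 210), c(0, 0))
  expect_equal(q$px[1], -q$px[2])
  expect_equal(q$py[1], -q$py[2])
  expect_equal(sqrt(q$px^2 + q$py^2), c(1, 1))
  expect_error(stereographic_projection(0, 91), "plunge")
})
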