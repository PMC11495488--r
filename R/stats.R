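#' Estimate log10 body mass from long-bone circumference
#'
#' `logBM = a * log10(circumference) + b`, with the scaling coefficients
#' supplied explicitly (they come from an external interspecific scaling
#' equation and are mandatory configuration — no defaults are invented).
#' When a specimen has estimates from both elements, average them with
#' [specimen_log_body_mass()].
#'
#' @param circumference bone circumference in mm (vectorized).
#' @param coefficients numeric `c(a, b)`.
#' @return log10 body mass (kg).
#' @export
estimate_log_body_mass <- function(circumference, coefficients) {
  if (is.null(coefficients) || length(coefficients) != 2 ||
      any(!is.finite(coefficients))) {
    stopf("`coefficients` (a, b) are required configuration; none are defaulted")
  }
  if (any(circumference <= 0)) stopf("circumference must be positive")
  coefficients[1] * log10(circumference) + coefficients[2]
}

#' @rdname estimate_log_body_mass
#' @param estimates numeric vector of per-element logBM estimates for one
#'   specimen (one or two values).
#' @export
specimen_log_body_mass <- function(estimates) {
  mean(estimates)
}

#' Coefficient of variation
#'
#' Sample standard deviation as a percentage of the mean.
#'
#' @param values numeric vector, length >= 2.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2) stopf("CV needs at least 2 values")
  m <- mean(values)
  if (m == 0) stopf("CV is undefined for zero-mean data")
  100 * sd(values) / m
}

#' Pairwise correlation matrix with p-values
#'
#' `pearson`: product-moment correlations. `partial`: partial correlations
#' controlling for all remaining variables, computed from the inverse
#' covariance matrix (`r_ij = -p_ij / sqrt(p_ii p_jj)`); p-values from the
#' t distribution with `n - 2 - g` degrees of freedom, `g` the number of
#' controlled variables.
#'
#' @param data a data frame of numeric columns.
#' @param mode `"pearson"` or `"partial"`.
#' @return A list with matrices `r` and `p` (unit diagonal, symmetric) and
#'   a tidy tibble `pairs`.
#' @export
correlation_matrix <- function(data, mode = c("pearson", "partial")) {
  mode <- match.arg(mode)
  x <- as.matrix(data[stats::complete.cases(data), , drop = FALSE])
  n <- nrow(x)
  k <- ncol(x)
  if (n < 4) stopf("need at least 4 complete rows")
  if (mode == "pearson") {
    r <- stats::cor(x)
    g <- 0
  } else {
    cv <- stats::cov(x)
    pm <- tryCatch(solve(cv), error = function(e) {
      stopf("singular covariance matrix: partial correlations are undefined")
    })
    dd <- 1 / sqrt(diag(pm))
    r <- -pm * outer(dd, dd)
    diag(r) <- 1
    g <- k - 2
  }
  df <- n - 2 - g
  tstat <- r * sqrt(df / pmax(1e-300, 1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df)
  diag(p) <- 0
  pairs <- which(upper.tri(r), arr.ind = TRUE)
  list(
    r = r, p = p,
    pairs = tibble::tibble(
      var1 = colnames(r)[pairs[, 1]], var2 = colnames(r)[pairs[, 2]],
      r = r[pairs], p = p[pairs]
    )
  )
}

#' Principal component analysis of the metric table
#'
#' Columns are centered (and unit-scaled iff `scale`), decomposed with
#' `prcomp`, and given a deterministic sign convention: the
#' largest-magnitude loading of each component is positive. Raw azimuth must
#' not be supplied; fold it first with [fold_azimuth()].
#'
#' @param data a data frame; `columns` selects the numeric variables.
#' @param columns character vector of column names.
#' @param scale logical; unit-variance scaling (default off, matching a PCA
#'   on raw values).
#' @return An object of class `trab_pca`: `scores`, `loadings`,
#'   `explained_variance` (fractions), `sdev`, `center`, `scale`.
#' @export
pca_metrics <- function(data, columns = NULL, scale = FALSE) {
  if (any(c("azimuth", "azimuth_raw") %in% columns)) {
    stopf("supply folded azimuth (fold_azimuth), never raw azimuth")
  }
  x <- if (is.null(columns)) data else data[, columns, drop = FALSE]
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < 3) stopf("need at least 3 complete rows")
  if (scale && any(vapply(x, function(c) var(c) == 0, TRUE))) {
    stopf("constant column cannot be unit-scaled")
  }
  fit <- stats::prcomp(as.matrix(x), center = TRUE, scale. = scale)
  flip <- apply(fit$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  fit$rotation <- sweep(fit$rotation, 2, flip, `*`)
  fit$x <- sweep(fit$x, 2, flip, `*`)
  structure(
    list(
      scores = tibble::as_tibble(fit$x),
      loadings = fit$rotation,
      explained_variance = fit$sdev^2 / sum(fit$sdev^2),
      sdev = fit$sdev,
      center = fit$center,
      scale = if (scale) fit$scale else FALSE
    ),
    class = "trab_pca"
  )
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected midrank H statistic with a chi-squared reference
#' distribution on `k - 1` degrees of freedom. Degenerate all-tied input
#' returns `H = 0, p = 1`.
#'
#' @param values numeric response.
#' @param groups grouping vector (same length).
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(as.vector(groups))
  if (nlevels(droplevels(groups)) < 2) stopf("need at least 2 nonempty groups")
  if (any(table(groups) == 0)) stopf("every group must be nonempty")
  if (length(unique(values)) == 1) {
    return(tibble::tibble(statistic = 0, df = nlevels(groups) - 1L,
                          p_value = 1))
  }
  kt <- stats::kruskal.test(values, groups)
  tibble::tibble(statistic = unname(kt$statistic),
                 df = unname(kt$parameter),
                 p_value = kt$p.value)
}

#' Dunn post-hoc test
#'
#' Pairwise mean-rank comparisons after a significant Kruskal-Wallis
#' omnibus test: `z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T)(1/n_i +
#' 1/n_j))` with the tie term `T = sum(t^3 - t) / (12 (N - 1))`; two-sided
#' p-values, optionally adjusted.
#'
#' @param values,groups as in [kruskal_wallis()].
#' @param adjustment `"none"` (the conventional default), `"bonferroni"`,
#'   or `"holm"`.
#' @param omnibus_p the Kruskal-Wallis p-value when run inside the pipeline;
#'   the call is refused if it is not below `alpha`. Omit for a standalone
#'   run (recorded in the `standalone` attribute, with a warning).
#' @param alpha significance gate for the omnibus test.
#' @return A tibble with one row per group pair: `group1`, `group2`, `z`,
#'   `p_value`, `p_adjusted`.
#' @export
dunn_posthoc <- function(values, groups,
                         adjustment = c("none", "bonferroni", "holm"),
                         omnibus_p = NULL, alpha = 0.05) {
  adjustment <- match.arg(adjustment)
  standalone <- is.null(omnibus_p)
  if (!standalone && omnibus_p >= alpha) {
    stopf("omnibus Kruskal-Wallis p = %.3g is not significant at alpha = %g; Dunn test refused",
          omnibus_p, alpha)
  }
  if (standalone) {
    warning("Dunn test run without a significant omnibus test (standalone mode)",
            call. = FALSE)
  }
  groups <- as.factor(as.vector(groups))
  n_tot <- length(values)
  rk <- rank(values)
  mean_rank <- tapply(rk, groups, mean)
  n_g <- tapply(rk, groups, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n_tot - 1))
  lv <- levels(groups)
  cmb <- utils::combn(lv, 2)
  z <- p <- numeric(ncol(cmb))
  for (i in seq_len(ncol(cmb))) {
    a <- cmb[1, i]; b <- cmb[2, i]
    se <- sqrt((n_tot * (n_tot + 1) / 12 - tie_term) *
                 (1 / n_g[[a]] + 1 / n_g[[b]]))
    z[i] <- (mean_rank[[a]] - mean_rank[[b]]) / se
    p[i] <- 2 * stats::pnorm(-abs(z[i]))
  }
  out <- tibble::tibble(
    group1 = cmb[1, ], group2 = cmb[2, ], z = z, p_value = p,
    p_adjusted = stats::p.adjust(p, method = adjustment)
  )
  attr(out, "standalone") <- standalone
  out
}

#' Allometric scaling regression with cross-validated degree selection
#'
#' Fits ordinary least squares polynomials of each candidate degree of `y`
#' on `x` (log10 body mass), choosing the degree with the lowest mean
#' k-fold cross-validated MSE (seeded fold shuffle). The linear fit is
#' always reported with its slope, 95% CI, and the comparison against the
#' metric's isometric reference slope (0 for unitless ratios, -1/3 for
#' TbN, +1/3 for linear dimensions): isometry is rejected when the
#' reference falls outside the CI.
#'
#' @param x predictor (log10 body mass).
#' @param y response (the metric, log10-transformed by the caller for
#'   slope/isometry work).
#' @param isometric_reference the expected isometric slope.
#' @param candidate_degrees polynomial degrees to compare.
#' @param k number of CV folds.
#' @param seed integer seed for the fold shuffle.
#' @return An object of class `trab_scaling`.
#' @export
scaling_regression <- function(x, y, isometric_reference = 0,
                               candidate_degrees = 1:4, k = 10, seed = 1) {
  n <- length(x)
  if (length(y) != n) stopf("x and y lengths differ")
  if (var(x) == 0) stopf("predictor has zero variance: slope is undefined")
  if (k > n) stopf("k = %d folds exceed n = %d points", k, n)
  if (n < 2 * k) stopf("need at least 2k points")
  if (length(candidate_degrees) == 0) stopf("no candidate degrees")
  folds <- with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  cv_mse <- vapply(candidate_degrees, function(d) {
    errs <- vapply(seq_len(k), function(f) {
      tr <- folds != f
      fit <- stats::lm(y[tr] ~ stats::poly(x[tr], degree = d, raw = TRUE))
      xp <- outer(x[!tr], seq_len(d), `^`)
      pred <- cbind(1, xp) %*% stats::coef(fit)
      mean((y[!tr] - pred)^2)
    }, 0)
    mean(errs)
  }, 0)
  # lowest mean CV MSE; numerically tied degrees resolve to the smallest
  tol <- max(1e-12, min(cv_mse) * 1e-8)
  chosen <- min(candidate_degrees[cv_mse <= min(cv_mse) + tol])
  lin <- stats::lm(y ~ x)
  ci <- stats::confint(lin, "x", level = 0.95)
  slope <- unname(stats::coef(lin)["x"])
  best <- stats::lm(y ~ stats::poly(x, degree = chosen, raw = TRUE))
  structure(
    list(
      chosen_degree = chosen,
      candidate_degrees = candidate_degrees,
      cv_mse = stats::setNames(cv_mse, paste0("degree_", candidate_degrees)),
      coefficients = stats::coef(best),
      linear_fit = lin,
      slope = slope,
      slope_ci = c(lower = ci[1], upper = ci[2]),
      isometric_reference = isometric_reference,
      isometry_rejected = isometric_reference < ci[1] ||
        isometric_reference > ci[2],
      k = k, seed = seed, n = n
    ),
    class = "trab_scaling"
  )
}

#' @export
print.trab_scaling <- function(x, ...) {
  cat(sprintf(
    paste0("<trab_scaling> n = %d, chosen degree %d (10-fold CV)\n",
           "  linear slope %.4f [%.4f, %.4f]; isometric reference %.3f %s\n"),
    x$n, x$chosen_degree, x$slope, x$slope_ci[1], x$slope_ci[2],
    x$isometric_reference,
    if (x$isometry_rejected) "(rejected)" else "(not rejected)"
  ))
  invisible(x)
}

#' Lambert equal-area lower-hemisphere projection
#'
#' Maps an axial orientation (azimuth, plunge) into the unit disk:
#' `r = sqrt(2) * sin((90 - plunge)/2)` (normalized so plunge 0 lies on the
#' unit circle), `px = r sin(azimuth)`, `py = r cos(azimuth)`. Vertical
#' orientations plot at the center.
#'
#' @param azimuth degrees in `[0, 360)` (vectorized).
#' @param plunge degrees in `[0, 90]`.
#' @return A tibble with columns `px`, `py`.
#' @export
stereographic_projection <- function(azimuth, plunge) {
  if (any(plunge < 0 | plunge > 90)) stopf("plunge must lie in [0, 90]")
  r <- sqrt(2) * sin((90 - plunge) * pi / 360)
  tibble::tibble(px = r * sin(azimuth * pi / 180),
                 py = r * cos(azimuth * pi / 180))
}
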