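#' Default per-group metric targets for the raccoon ontogenetic cohort
#'
#' Group means and coefficients of variation of the five univariate
#' trabecular metrics (DA, BV/TV, TbTh, TbSp, TbN) for the humerus and femur
#' in the five age groups, as published for the *Procyon lotor* ontogenetic
#' series. Thickness and spacing are in millimetres.
#'
#' @return A tibble with columns `age_group`, `element`, `metric`, `mean`,
#'   `cv` (cv in percent).
#' @export
default_cohort_targets <- function() {
  groups <- age_group_levels()
  hum_mean <- rbind(
    c(0.19, 0.276, 0.135, 0.311, 1.71),
    c(0.342, 0.437, 0.185, 0.315, 1.87),
    c(0.355, 0.369, 0.177, 0.354, 1.69),
    c(0.351, 0.314, 0.174, 0.386, 1.51),
    c(0.386, 0.311, 0.174, 0.419, 1.45)
  )
  fem_mean <- rbind(
    c(0.16, 0.358, 0.137, 0.245, 2.13),
    c(0.333, 0.477, 0.214, 0.280, 1.86),
    c(0.411, 0.468, 0.252, 0.319, 1.62),
    c(0.399, 0.412, 0.228, 0.358, 1.52),
    c(0.434, 0.404, 0.226, 0.361, 1.57)
  )
  hum_cv <- rbind(
    c(22.1, 22.7, 11.3, 14.1, 19.5),
    c(15.6, 14.6, 15.8, 10.8, 11.8),
    c(16.0, 20.5, 7.59, 11.8, 12.6),
    c(20.2, 25.2, 13.3, 10.8, 10.7),
    c(19.2, 17.1, 8.9, 8.7, 10.4)
  )
  fem_cv <- rbind(
    c(42.1, 29.1, 12.9, 20.0, 21.8),
    c(20.7, 12.2, 27.6, 9.61, 13.9),
    c(19.5, 16.4, 26.1, 10.9, 13.2),
    c(14.6, 13.1, 10.6, 5.77, 6.14),
    c(14.0, 12.5, 13.1, 8.6, 17.1)
  )
  metrics <- c("da", "bvtv", "tbth", "tbsp", "tbn")
  build <- function(el, m, v) {
    tibble::tibble(
      age_group = rep(groups, each = length(metrics)),
      element = el,
      metric = rep(metrics, times = length(groups)),
      mean = as.vector(t(m)),
      cv = as.vector(t(v))
    )
  }
  dplyr::bind_rows(build("humerus", hum_mean, hum_cv),
                   build("femur", fem_mean, fem_cv))
}

#' @export
#' @rdname default_cohort_targets
age_group_levels <- function() {
  c("2mo", "4-12mo", "14-24mo", "26-38mo", "46+mo")
}

default_logbm_targets <- function() {
  tibble::tibble(
    age_group = age_group_levels(),
    mean = c(0.12, 0.75, 0.85, 0.90, 0.95),
    cv = c(30, 10, 8, 8, 8)
  )
}

default_orientation_targets <- function() {
  groups <- age_group_levels()
  dplyr::bind_rows(
    tibble::tibble(age_group = groups, element = "humerus",
                   azimuth_mean = c(0, 0, 0, 0, 0),
                   azimuth_sd = c(25, 35, 45, 45, 45),
                   plunge_mean = c(20, 70, 75, 78, 80),
                   plunge_sd = c(20, 10, 8, 8, 8)),
    tibble::tibble(age_group = groups, element = "femur",
                   azimuth_mean = c(0, 0, 0, 0, 0),
                   azimuth_sd = c(25, 30, 45, 45, 45),
                   plunge_mean = c(15, 35, 72, 75, 78),
                   plunge_sd = c(20, 15, 8, 8, 8))
  )
}

#' Specification of a simulated ontogenetic cohort
#'
#' @param targets per-group metric means and CVs, as from
#'   [default_cohort_targets()].
#' @param sizes per-group sample sizes; the default (13, 11, 10, 7, 14)
#'   matches the study's five age groups.
#' @param logbm per-group mean and CV of log10 body mass (kg).
#' @param orientation per-group azimuth/plunge location and spread (degrees);
#'   azimuth follows a wrapped normal law, plunge a normal law reflected into
#'   `[0, 90]`.
#' @param noise_law `"lognormal"` (default; all metrics are strictly
#'   positive) or `"normal"`.
#' @param seed integer RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(targets = default_cohort_targets(),
                        sizes = c(13, 11, 10, 7, 14),
                        logbm = default_logbm_targets(),
                        orientation = default_orientation_targets(),
                        noise_law = c("lognormal", "normal"),
                        seed = 1) {
  noise_law <- match.arg(noise_law)
  if (length(sizes) != length(age_group_levels()) || any(sizes < 1)) {
    stopf("`sizes` must give a positive size for each of the %d age groups",
          length(age_group_levels()))
  }
  if (any(targets$cv < 0) || any(logbm$cv < 0)) {
    stopf("coefficients of variation must be >= 0")
  }
  structure(
    list(targets = targets, sizes = as.integer(sizes), logbm = logbm,
         orientation = orientation, noise_law = noise_law,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# n draws from a law with exact mean `m` and coefficient of variation
# `cv` percent (log-normal by default; mean is the arithmetic mean).
draw_mean_cv <- function(n, m, cv, law = "lognormal") {
  if (cv == 0) return(rep(m, n))
  if (law == "lognormal") {
    s2 <- log(1 + (cv / 100)^2)
    rlnorm(n, meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
  } else {
    rnorm(n, mean = m, sd = m * cv / 100)
  }
}

#' Simulate an ontogenetic cohort table
#'
#' Draws one humeral and one femoral metric vector per specimen from the
#' group targets (log-normal noise with the target mean and CV), a shared
#' log10 body mass per specimen, and a primary-orientation axis
#' (azimuth/plunge) from the wrapped group law. Deterministic for a fixed
#' seed.
#'
#' @param spec a [cohort_spec()].
#' @return A tibble with one row per specimen x element: `specimen_id`,
#'   `age_group`, `element`, `side`, `logbm`, `da`, `bvtv`, `tbth`, `tbsp`,
#'   `tbn` (tbth/tbsp in mm, tbn per mm), `azimuth`, `plunge` (degrees).
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- age_group_levels()
  with_seed(spec$seed, {
    rows <- purrr::map2(groups, spec$sizes, function(g, n) {
      ids <- sprintf("%s_S%02d", gsub("[-+]", "", g), seq_len(n))
      lb <- spec$logbm[spec$logbm$age_group == g, ]
      logbm <- draw_mean_cv(n, lb$mean, lb$cv, spec$noise_law)
      purrr::map(c("humerus", "femur"), function(el) {
        tg <- spec$targets[spec$targets$age_group == g &
                             spec$targets$element == el, ]
        met <- lapply(stats::setNames(tg$metric, tg$metric), function(m) {
          draw_mean_cv(n, tg$mean[tg$metric == m], tg$cv[tg$metric == m],
                       spec$noise_law)
        })
        ori <- spec$orientation[spec$orientation$age_group == g &
                                  spec$orientation$element == el, ]
        az <- (ori$azimuth_mean + rnorm(n, 0, ori$azimuth_sd)) %% 360
        pl <- abs(ori$plunge_mean + rnorm(n, 0, ori$plunge_sd))
        pl <- ifelse(pl > 90, 180 - pl, pl)
        tibble::tibble(
          specimen_id = ids, age_group = g, element = el, side = "right",
          logbm = logbm, da = met$da, bvtv = met$bvtv, tbth = met$tbth,
          tbsp = met$tbsp, tbn = met$tbn, azimuth = az, plunge = pl
        )
      }) |> dplyr::bind_rows()
    })
    dplyr::bind_rows(rows) |>
      dplyr::mutate(age_group = factor(.data$age_group, levels = groups)) |>
      dplyr::arrange(.data$age_group, .data$specimen_id, .data$element)
  })
}
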