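metric_columns <- function() c("da", "bvtv", "tbth", "tbsp", "tbn")

isometric_references <- function() {
  c(da = 0, bvtv = 0, tbth = 1 / 3, tbsp = 1 / 3, tbn = -1 / 3)
}

#' Per-group summary tables of the cohort metrics
#'
#' @param table a cohort tibble (see [run_cohort_analysis()]).
#' @return A tibble with one row per age group x element: `n` and the mean
#'   (or CV, in percent) of each metric.
#' @export
cohort_group_means <- function(table) {
  table |>
    dplyr::group_by(.data$age_group, .data$element) |>
    dplyr::summarise(n = dplyr::n(),
                     dplyr::across(dplyr::all_of(metric_columns()), mean),
                     .groups = "drop")
}

#' @rdname cohort_group_means
#' @export
cohort_group_cvs <- function(table) {
  table |>
    dplyr::group_by(.data$age_group, .data$element) |>
    dplyr::summarise(
      n = dplyr::n(),
      dplyr::across(dplyr::all_of(metric_columns()), coefficient_of_variation),
      .groups = "drop")
}

#' Run the full cohort-level statistics stage
#'
#' Given a cohort table (one row per specimen x element, as produced by
#' [simulate_cohort()] or the measurement pipeline), computes per-group
#' means and coefficients of variation, Kruskal-Wallis tests per metric
#' (with Dunn follow-ups where the omnibus test is significant at `alpha`),
#' correlation matrices per element, a PCA per element on body mass, the
#' five metrics, folded azimuth and plunge, allometric log-log regressions
#' against body mass with isometry comparison, and equal-area projection
#' coordinates of the primary orientations.
#'
#' @param table the cohort tibble; required columns `specimen_id`,
#'   `age_group`, `element`, `logbm`, `da`, `bvtv`, `tbth`, `tbsp`, `tbn`,
#'   `azimuth`, `plunge`.
#' @param alpha significance level gating the Dunn tests.
#' @param k CV folds for degree selection.
#' @param candidate_degrees polynomial degrees compared by CV.
#' @param adjustment Dunn p adjustment (`"none"`, `"bonferroni"`, `"holm"`).
#' @param pca_scale unit-variance scaling flag for the PCA (default off:
#'   raw values).
#' @param correlation_mode `"pearson"` or `"partial"`.
#' @param seed global seed; stage seeds are derived deterministically.
#' @return An object of class `trab_report` (a named list of tibbles and
#'   fitted objects).
#' @export
run_cohort_analysis <- function(table, alpha = 0.05, k = 10,
                                candidate_degrees = 1:4,
                                adjustment = "none", pca_scale = FALSE,
                                correlation_mode = "pearson", seed = 1) {
  needed <- c("specimen_id", "age_group", "element", "logbm",
              metric_columns(), "azimuth", "plunge")
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols) > 0) {
    stopf("cohort table lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  if (nrow(table) == 0) stopf("empty cohort table")
  table <- dplyr::mutate(table, azimuth_fold = fold_azimuth(.data$azimuth))
  test_cols <- c(metric_columns(), "azimuth_fold", "plunge")

  group_means <- cohort_group_means(table)
  group_cvs <- cohort_group_cvs(table)

  elements <- unique(table$element)
  kw <- purrr::map(elements, function(el) {
    sub <- table[table$element == el, ]
    purrr::map(test_cols, function(m) {
      res <- kruskal_wallis(sub[[m]], sub$age_group)
      dplyr::mutate(res, element = el, metric = m, .before = 1)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  kw_logbm <- table |>
    dplyr::distinct(.data$specimen_id, .data$age_group, .data$logbm)
  kw <- dplyr::bind_rows(
    kw,
    dplyr::mutate(kruskal_wallis(kw_logbm$logbm, kw_logbm$age_group),
                  element = "both", metric = "logbm", .before = 1)
  )

  dunn <- kw |>
    dplyr::filter(.data$p_value < alpha, .data$element != "both") |>
    purrr::pmap(function(element, metric, p_value, ...) {
      sub <- table[table$element == element, ]
      res <- dunn_posthoc(sub[[metric]], sub$age_group,
                          adjustment = adjustment, omnibus_p = p_value,
                          alpha = alpha)
      dplyr::mutate(res, element = element, metric = metric, .before = 1)
    }) |> dplyr::bind_rows()

  correlations <- purrr::map(stats::setNames(elements, elements), function(el) {
    correlation_matrix(table[table$element == el, metric_columns()],
                       mode = correlation_mode)
  })

  pca <- purrr::map(stats::setNames(elements, elements), function(el) {
    pca_metrics(table[table$element == el, ],
                columns = c("logbm", metric_columns(), "azimuth_fold",
                            "plunge"),
                scale = pca_scale)
  })

  refs <- isometric_references()
  regressions <- purrr::map(stats::setNames(elements, elements), function(el) {
    sub <- table[table$element == el, ]
    purrr::map(stats::setNames(metric_columns(), metric_columns()),
               function(m) {
      scaling_regression(sub$logbm, log10(sub[[m]]),
                         isometric_reference = refs[[m]],
                         candidate_degrees = candidate_degrees,
                         k = min(k, floor(nrow(sub) / 2)),
                         seed = derive_seed(seed, paste0("scaling_", el, "_", m)))
    })
  })

  projection <- dplyr::bind_cols(
    table[, c("specimen_id", "age_group", "element", "da")],
    stereographic_projection(table$azimuth, table$plunge)
  )

  structure(
    list(group_means = group_means, group_cvs = group_cvs,
         kruskal_wallis = kw, dunn = dunn, correlations = correlations,
         pca = pca, regressions = regressions, projection = projection,
         table = table,
         config = list(alpha = alpha, k = k,
                       candidate_degrees = candidate_degrees,
                       adjustment = adjustment, pca_scale = pca_scale,
                       correlation_mode = correlation_mode, seed = seed)),
    class = "trab_report"
  )
}

#' @export
print.trab_report <- function(x, ...) {
  cat(sprintf(
    paste0("<trab_report> %d specimen-element rows, %d age groups\n",
           "  %d Kruskal-Wallis tests (%d significant at alpha = %g), ",
           "%d Dunn pair rows\n"),
    nrow(x$table), length(unique(x$table$age_group)),
    nrow(x$kruskal_wallis),
    sum(x$kruskal_wallis$p_value < x$config$alpha),
    x$config$alpha, nrow(x$dunn)
  ))
  invisible(x)
}
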