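#' Read a pipeline configuration file
#'
#' YAML (or JSON) configuration holding the stage parameters and the global
#' seed. Every stochastic stage derives its own seed deterministically from
#' the global seed and the stage name.
#'
#' @param path YAML or JSON file.
#' @return A named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("no such config: %s", path)
  if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

config_get <- function(config, name, default = NULL) {
  config[[name]] %||% default
}

#' Simulate-stage entry point: write phantoms or a cohort to disk
#'
#' `simulate.kind = "phantoms"` writes binary rod-lattice TIFF stacks plus a
#' ground-truth CSV; `"whole_bones"` writes grayscale mocks, label stacks
#' and a landmark CSV; `"cohort"` writes the cohort metric table CSV. A
#' manifest JSON records the configuration hash, seed and file list.
#'
#' @param config configuration list (see `read_pipeline_config`).
#' @param out_dir output directory (created if missing).
#' @param seed global seed; overrides `config$seed`.
#' @param force overwrite an existing manifest.
#' @return The manifest, invisibly.
#' @export
pipeline_simulate <- function(config, out_dir, seed = NULL, force = FALSE) {
  seed <- as.integer(seed %||% config_get(config, "seed", 1))
  sim <- config_get(config, "simulate", list())
  kind <- config_get(sim, "kind", "phantoms")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path) && !force) {
    stopf("%s exists; use force = TRUE to overwrite", manifest_path)
  }
  files <- character()
  if (kind == "phantoms") {
    n <- config_get(sim, "n", 3)
    ph <- config_get(sim, "phantom", list())
    truth <- purrr::map(seq_len(n), function(i) {
      sp <- phantom_spec(
        shape = unlist(config_get(ph, "shape", c(48, 48, 48))),
        voxel_size = config_get(ph, "voxel_size", 30),
        target_bvtv = config_get(ph, "target_bvtv", 0.3),
        strut_radius = config_get(ph, "strut_radius", 3),
        mean_axis = unlist(config_get(ph, "mean_axis", c(0, 0, 1))),
        kappa = config_get(ph, "kappa", 0),
        seed = derive_seed(seed, paste0("phantom_", i))
      )
      gen <- generate_rod_phantom(sp)
      f <- file.path(out_dir, sprintf("phantom_%02d.tif", i))
      write_stack(gen$volume, f)
      files <<- c(files, f)
      tibble::tibble(
        specimen_id = sprintf("phantom_%02d", i), file = basename(f),
        achieved_bvtv = gen$truth$achieved_bvtv,
        strut_radius = gen$truth$strut_radius,
        kappa = sp$kappa, n_struts = gen$truth$n_struts, seed = sp$seed
      )
    }) |> dplyr::bind_rows()
    truth_file <- file.path(out_dir, "ground_truth.csv")
    utils::write.csv(truth, truth_file, row.names = FALSE)
    files <- c(files, truth_file)
  } else if (kind == "whole_bones") {
    n <- config_get(sim, "n", 2)
    wb <- config_get(sim, "whole_bone", list())
    lms <- purrr::map(seq_len(n), function(i) {
      sp <- whole_bone_spec(
        shape = unlist(config_get(wb, "shape", c(96, 96, 96))),
        outer_radius = config_get(wb, "outer_radius", 40),
        cortical_thickness = config_get(wb, "cortical_thickness", 5),
        head_center = unlist(config_get(wb, "head_center", c(47, 47, 52))),
        noise_sd = config_get(wb, "noise_sd", 0.05),
        voxel_size = config_get(wb, "voxel_size", 30),
        seed = derive_seed(seed, paste0("bone_", i))
      )
      gen <- generate_whole_bone(sp)
      fg <- file.path(out_dir, sprintf("bone_%02d.tif", i))
      fl <- file.path(out_dir, sprintf("bone_%02d_labels.tif", i))
      write_stack(gen$grayscale, fg)
      write_stack(trab_volume(gen$labels * 100, sp$voxel_size,
                              kind = "grayscale"), fl)
      files <<- c(files, fg, fl)
      lm <- landmark_matrix(gen$landmarks)
      tibble::tibble(specimen_id = sprintf("bone_%02d", i),
                     landmark_name = rownames(lm),
                     x = lm[, 1], y = lm[, 2], z = lm[, 3])
    }) |> dplyr::bind_rows()
    lm_file <- file.path(out_dir, "landmarks.csv")
    utils::write.csv(lms, lm_file, row.names = FALSE)
    files <- c(files, lm_file)
  } else if (kind == "cohort") {
    spec <- cohort_spec(seed = derive_seed(seed, "cohort"))
    cohort <- simulate_cohort(spec)
    f <- file.path(out_dir, "cohort.csv")
    utils::write.csv(cohort, f, row.names = FALSE)
    files <- c(files, f)
  } else {
    stopf("unknown simulate.kind `%s` (field: simulate.kind)", kind)
  }
  manifest <- list(kind = kind, seed = seed, files = basename(files),
                   config_hash = rlang::hash(config))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Measure-stage entry point: volumes to a metrics CSV
#'
#' For phantom batches the ROI is the largest grid-inscribed sphere; for
#' whole-bone mocks the full chain runs: landmark orientation, interior
#' box, maximal cortex-free sphere, Otsu segmentation, purification, then
#' the full metric vector. Per-specimen failures are recorded and skipped.
#'
#' @param in_dir directory holding a `manifest.json` from
#'   [pipeline_simulate()].
#' @param config configuration list; the `measure` block may set
#'   `n_directions`, `line_spacing`, `tbn_method`.
#' @param out_csv output metrics CSV path.
#' @param seed global seed.
#' @return The metrics tibble; failed specimens are in the `"errors"`
#'   attribute.
#' @export
pipeline_measure <- function(in_dir, config = list(), out_csv = NULL,
                             seed = NULL) {
  manifest_path <- file.path(in_dir, "manifest.json")
  if (!file.exists(manifest_path)) stopf("no manifest.json in %s", in_dir)
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  seed <- as.integer(seed %||% config_get(config, "seed", manifest$seed))
  ms <- config_get(config, "measure", list())
  n_directions <- config_get(ms, "n_directions", 256)
  line_spacing <- config_get(ms, "line_spacing", 2)
  tbn_method <- config_get(ms, "tbn_method", "plate_model")
  errors <- list()
  measure_one <- function(id, fun) {
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e) {
      errors[[id]] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(res)) {
      res$specimen_id <- id
      res$seconds <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    }
    res
  }
  rows <- list()
  if (manifest$kind == "phantoms") {
    tifs <- grep("^phantom_.*\\.tif$", manifest$files, value = TRUE)
    for (f in tifs) {
      id <- sub("\\.tif$", "", f)
      rows[[id]] <- measure_one(id, function() {
        vol <- read_stack(file.path(in_dir, f))
        d <- dim(vol$values)
        roi <- spherical_roi((c(d[2], d[1], d[3]) - 1) / 2,
                             min(d) / 2 - 2)
        seg <- segment_roi(vol, roi)
        seg$foreground <- purify(seg$foreground) &
          (seg$foreground | seg$background)
        seg$background <- (seg$foreground | seg$background) & !seg$foreground
        compute_all_metrics(seg, n_directions = n_directions,
                            line_spacing = line_spacing,
                            seed = derive_seed(seed, id),
                            tbn_method = tbn_method)
      })
    }
  } else if (manifest$kind == "whole_bones") {
    lms <- utils::read.csv(file.path(in_dir, "landmarks.csv"))
    tifs <- grep("^bone_[0-9]+\\.tif$", manifest$files, value = TRUE)
    for (f in tifs) {
      id <- sub("\\.tif$", "", f)
      rows[[id]] <- measure_one(id, function() {
        vol <- read_stack(file.path(in_dir, f))
        lab <- read_stack(file.path(in_dir, sub("\\.tif$", "_labels.tif", f)))
        lmrows <- lms[lms$specimen_id == id, ]
        lmset <- landmark_set(
          proximal = unlist(lmrows[lmrows$landmark_name == "proximal", c("x", "y", "z")]),
          distal = unlist(lmrows[lmrows$landmark_name == "distal", c("x", "y", "z")]),
          lateral_a = unlist(lmrows[lmrows$landmark_name == "lateral_a", c("x", "y", "z")]),
          lateral_b = unlist(lmrows[lmrows$landmark_name == "lateral_b", c("x", "y", "z")]),
          articular = unlist(lmrows[lmrows$landmark_name == "articular", c("x", "y", "z")])
        )
        tr <- orientation_transform(lmset)
        vol_o <- apply_transform(vol, tr, "nearest")
        lab_o <- apply_transform(lab, tr, "nearest")
        off <- attr(lab_o, "offset")
        cortical <- lab_o$values >= 150
        center <- transform_points(lmset$proximal, tr) - off
        box <- interior_box(cortical, center)
        roi <- expand_sphere(box, cortical)
        seg <- segment_roi(vol_o, roi)
        sph <- seg$foreground | seg$background
        seg$foreground <- purify(seg$foreground) & sph
        seg$background <- sph & !seg$foreground
        compute_all_metrics(seg, n_directions = n_directions,
                            line_spacing = line_spacing,
                            seed = derive_seed(seed, id),
                            tbn_method = tbn_method)
      })
    }
  } else {
    stopf("manifest kind `%s` holds no volumes to measure", manifest$kind)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0) {
    out <- dplyr::relocate(out, "specimen_id")
  }
  attr(out, "errors") <- errors
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Analyze-stage entry point: metrics CSV to a report bundle on disk
#'
#' @param metrics_csv cohort metrics CSV (one row per specimen x element;
#'   columns as in [run_cohort_analysis()], or joinable to `metadata_csv`
#'   by `specimen_id`).
#' @param out_dir report output directory.
#' @param config configuration list; the `analyze` block may set `alpha`,
#'   `k`, `degrees`, `adjustment`, `pca_scale`, `correlation_mode`, and
#'   `mass_coefficients` (a, b) used to fill `logbm` from a `circumference`
#'   column when `logbm` is absent.
#' @param metadata_csv optional per-specimen metadata joined on
#'   `specimen_id`.
#' @param seed global seed.
#' @return The [run_cohort_analysis()] report, invisibly.
#' @export
pipeline_analyze <- function(metrics_csv, out_dir, config = list(),
                             metadata_csv = NULL, seed = NULL) {
  if (!file.exists(metrics_csv)) stopf("no such metrics CSV: %s", metrics_csv)
  table <- tibble::as_tibble(utils::read.csv(metrics_csv))
  if (nrow(table) == 0) stopf("empty metrics CSV")
  if (!is.null(metadata_csv)) {
    meta <- utils::read.csv(metadata_csv)
    if (!"specimen_id" %in% names(meta)) {
      stopf("metadata CSV lacks column: specimen_id")
    }
    table <- dplyr::left_join(table, tibble::as_tibble(meta),
                              by = "specimen_id")
  }
  an <- config_get(config, "analyze", list())
  seed <- as.integer(seed %||% config_get(config, "seed", 1))
  if (!"logbm" %in% names(table)) {
    cf <- unlist(config_get(an, "mass_coefficients", NULL))
    if (!"circumference" %in% names(table)) {
      stopf("cohort table lacks column(s): logbm (or circumference + analyze.mass_coefficients)")
    }
    est <- estimate_log_body_mass(table$circumference, cf)
    table$logbm <- stats::ave(est, table$specimen_id,
                              FUN = specimen_log_body_mass)
  }
  if ("age_group" %in% names(table)) {
    table$age_group <- factor(table$age_group,
                              levels = intersect(age_group_levels(),
                                                 unique(table$age_group)))
  }
  report <- run_cohort_analysis(
    table,
    alpha = config_get(an, "alpha", 0.05),
    k = config_get(an, "k", 10),
    candidate_degrees = unlist(config_get(an, "degrees", 1:4)),
    adjustment = config_get(an, "adjustment", "none"),
    pca_scale = config_get(an, "pca_scale", FALSE),
    correlation_mode = config_get(an, "correlation_mode", "pearson"),
    seed = derive_seed(seed, "analyze")
  )
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(report$group_means, file.path(out_dir, "group_means.csv"),
                   row.names = FALSE)
  utils::write.csv(report$group_cvs, file.path(out_dir, "group_cvs.csv"),
                   row.names = FALSE)
  utils::write.csv(report$kruskal_wallis,
                   file.path(out_dir, "kruskal_wallis.csv"), row.names = FALSE)
  utils::write.csv(report$dunn, file.path(out_dir, "dunn.csv"),
                   row.names = FALSE)
  utils::write.csv(report$projection, file.path(out_dir, "projection.csv"),
                   row.names = FALSE)
  for (el in names(report$correlations)) {
    utils::write.csv(report$correlations[[el]]$pairs,
                     file.path(out_dir, sprintf("correlations_%s.csv", el)),
                     row.names = FALSE)
  }
  reg_glance <- purrr::imap(report$regressions, function(fits, el) {
    purrr::imap(fits, function(f, m) {
      dplyr::mutate(glance(f), element = el, metric = m, .before = 1)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  utils::write.csv(reg_glance, file.path(out_dir, "regressions.csv"),
                   row.names = FALSE)
  summary <- list(
    config = report$config,
    kruskal_wallis = report$kruskal_wallis,
    dunn_pairs = nrow(report$dunn),
    regressions = reg_glance,
    pca_explained = purrr::map(report$pca, "explained_variance")
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}
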