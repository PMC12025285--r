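#' Write a cohort to a directory of delimited text files
#'
#' One `<modality>_<timepoint>.csv` per cell (subjects x features, header
#' row of feature names), a `labels.csv` (subject_id, label) and, when the
#' cohort carries planted ground truth, a `ground_truth.json`.
#'
#' @param data a [cohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(data, dir) {
  stopifnot(inherits(data, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in seq_len(n_modalities(data))) {
    for (t in seq_len(n_timepoints(data))) {
      path <- file.path(dir, sprintf("%s_%s.csv", data$modality_names[m],
                                     data$timepoint_names[t]))
      write.csv(data$features[[m]][[t]], path, row.names = FALSE)
    }
  }
  write.csv(data.frame(subject_id = data$subject_ids, label = data$labels),
            file.path(dir, "labels.csv"), row.names = FALSE)
  gt <- attr(data, "ground_truth")
  if (!is.null(gt)) {
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"))
  }
  invisible(dir)
}

#' Read a cohort from a directory or an explicit cell map
#'
#' With a directory argument, expects the layout written by
#' [write_cohort()]: one `<modality>_<timepoint>.csv` per (modality, time
#' point) cell plus `labels.csv`. Alternatively pass `cells`, a nested
#' named list `cells[[modality]][[timepoint]] = path`. The modality x
#' timepoint grid must be complete (missing cells are an error; imputation
#' is out of scope), all cells must agree on dimensions, and labels are
#' coerced to -1/+1 with the mapping reported.
#'
#' @param dir directory containing the cohort files.
#' @param cells optional nested named list of file paths, overriding `dir`
#'   scanning.
#' @param labels_path path to the labels file (default
#'   `file.path(dir, "labels.csv")`).
#' @param quiet suppress the label-mapping message.
#' @return a [cohort()]; a `ground_truth.json` found alongside is attached
#'   as the `ground_truth` attribute.
#' @export
read_cohort <- function(dir = NULL, cells = NULL, labels_path = NULL,
                        quiet = FALSE) {
  if (is.null(cells)) {
    if (is.null(dir)) abort("supply `dir` or `cells`")
    files <- setdiff(list.files(dir, pattern = "\\.csv$"), "labels.csv")
    if (length(files) == 0L) abort(sprintf("no cell files found in %s", dir))
    parts <- regmatches(files, regexec("^(.*)_([^_]+)\\.csv$", files))
    if (any(lengths(parts) != 3L)) {
      abort("cell files must be named <modality>_<timepoint>.csv")
    }
    mods <- vapply(parts, `[`, character(1), 2)
    tps <- vapply(parts, `[`, character(1), 3)
    cells <- lapply(stats::setNames(unique(mods), unique(mods)), function(m) {
      tp_here <- tps[mods == m]
      stats::setNames(as.list(file.path(dir, files[mods == m])), tp_here)[order(tp_here)]
    })
  }
  mod_names <- names(cells)
  tp_sets <- lapply(cells, names)
  tp_names <- tp_sets[[1]]
  for (m in seq_along(cells)) {
    if (!setequal(tp_sets[[m]], tp_names)) {
      abort(sprintf("missing cell: modality '%s' lacks timepoint(s) %s",
                    mod_names[m],
                    paste(setdiff(tp_names, tp_sets[[m]]), collapse = ", ")))
    }
    cells[[m]] <- cells[[m]][tp_names]
  }
  feats <- lapply(cells, function(paths) {
    lapply(paths, function(p) {
      if (!file.exists(p)) abort(sprintf("missing cell: file not found: %s", p))
      as.matrix(read.csv(p, check.names = FALSE))
    })
  })
  dims <- do.call(rbind, lapply(seq_along(feats), function(m) {
    do.call(rbind, lapply(seq_along(feats[[m]]), function(t) {
      data.frame(m = m, t = t, n = nrow(feats[[m]][[t]]),
                 d = ncol(feats[[m]][[t]]),
                 file = as.character(cells[[m]][[t]]))
    }))
  }))
  if (length(unique(dims$n)) != 1L || length(unique(dims$d)) != 1L) {
    off <- dims[dims$n != dims$n[1] | dims$d != dims$d[1], ]
    abort(sprintf("dimension mismatch in file(s): %s",
                  paste(off$file, collapse = ", ")))
  }
  labels_path <- labels_path %||% file.path(dir %||% ".", "labels.csv")
  if (!file.exists(labels_path)) abort(sprintf("labels file not found: %s", labels_path))
  lab_df <- read.csv(labels_path)
  if (nrow(lab_df) != dims$n[1]) {
    abort(sprintf("dimension mismatch in file(s): %s (%d labels for %d subjects)",
                  labels_path, nrow(lab_df), dims$n[1]))
  }
  labels <- coerce_labels(lab_df$label, quiet = quiet)
  out <- cohort(feats, labels,
                modality_names = mod_names, timepoint_names = tp_names,
                feature_names = colnames(feats[[1]][[1]]),
                subject_ids = as.character(lab_df$subject_id))
  gt_path <- if (!is.null(dir)) file.path(dir, "ground_truth.json") else ""
  if (nzchar(gt_path) && file.exists(gt_path)) {
    gt <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    attr(out, "ground_truth") <- lapply(gt, as.integer)
  }
  out
}

#' Read an ROI name map
#'
#' A two-column delimited file mapping feature index (1..d) to a region
#' name, e.g. an AAL atlas table. The packaged 90-region AAL map is at
#' `system.file("extdata", "aal90_regions.tsv", package = "hyperfuse")`.
#'
#' @param path file path; defaults to the packaged AAL-90 table.
#' @return a tibble with columns `index`, `name`.
#' @export
read_roi_names <- function(path = NULL) {
  path <- path %||% system.file("extdata", "aal90_regions.tsv",
                                package = "hyperfuse")
  df <- read.csv(path, sep = "\t", header = TRUE)
  names(df)[1:2] <- c("index", "name")
  tibble::as_tibble(df[, 1:2])
}

#' Read a run configuration
#'
#' YAML or JSON file with (all optional unless noted) fields: `data` (a
#' cohort directory) or `simulate` (arguments to [sim_spec()]), `params`
#' (arguments to [hf_params()]), `folds`, `seed`, `weight_grid_step`,
#' `svm_c`, `inner_folds`, `top_k`, `roi_names` (path).
#'
#' @param path configuration file path.
#' @return a named list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg$params <- do.call(hf_params, as.list(cfg$params %||% list()))
  cfg$folds <- cfg$folds %||% 10
  cfg$seed <- cfg$seed %||% 1
  cfg$weight_grid_step <- cfg$weight_grid_step %||% 0.1
  cfg$svm_c <- cfg$svm_c %||% 1
  cfg$inner_folds <- cfg$inner_folds %||% 10
  cfg$top_k <- cfg$top_k %||% 10
  cfg
}

#' Load the cohort named by a run configuration
#'
#' @param cfg a list from [read_run_config()].
#' @return a [cohort()]: read from `cfg$data` when given, otherwise
#'   simulated from `cfg$simulate` under `cfg$seed`.
#' @export
load_cohort <- function(cfg) {
  if (!is.null(cfg$data)) {
    read_cohort(cfg$data)
  } else if (!is.null(cfg$simulate)) {
    simulate_cohort(do.call(sim_spec, as.list(cfg$simulate)), seed = cfg$seed)
  } else {
    abort("config must name a `data` directory or a `simulate` block")
  }
}

#' Write a reproducibility manifest
#'
#' JSON echo of the run configuration plus seed, package version and
#' timings, written alongside the outputs of a run.
#'
#' @param cfg run configuration list.
#' @param dir output directory.
#' @param timings named numeric vector of elapsed seconds.
#' @return the manifest path, invisibly.
#' @export
write_manifest <- function(cfg, dir, timings = NULL) {
  manifest <- list(
    config = cfg[setdiff(names(cfg), "params")],
    params = unclass(cfg$params),
    seed = cfg$seed,
    package_version = as.character(packageVersion("hyperfuse")),
    timings_sec = as.list(timings)
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write the output tables of a cross-validated run
#'
#' Emits `metrics.csv` (pooled row plus per-fold rows), `roc_points.csv`
#' and `stability.csv` into `dir`.
#'
#' @param cv an [hf_cv()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cv_outputs <- function(cv, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pooled <- dplyr::mutate(cv$pooled, fold = "pooled", .before = 1)
  by_fold <- dplyr::mutate(cv$by_fold, fold = as.character(.data$fold))
  metrics <- dplyr::bind_rows(pooled, by_fold)
  write.csv(metrics, file.path(dir, "metrics.csv"), row.names = FALSE)
  write.csv(cv$roc, file.path(dir, "roc_points.csv"), row.names = FALSE)
  write.csv(cv$stability, file.path(dir, "stability.csv"), row.names = FALSE)
  invisible(dir)
}
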