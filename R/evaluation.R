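#' Binary classification metrics
#'
#' The positive class is `+1`. Accuracy, sensitivity (TP / (TP + FN)),
#' specificity (TN / (TN + FP)), precision and F1 (harmonic mean of
#' precision and recall) are computed from the confusion matrix; AUC is
#' the area under the empirical ROC curve by the trapezoidal rule when
#' `scores` are supplied.
#'
#' @param truth vector of true labels (-1/+1); both classes must be
#'   present.
#' @param pred vector of predicted labels (-1/+1).
#' @param scores optional decision scores (larger means more +1-like);
#'   required for AUC and ROC points.
#' @return a one-row tibble with columns `tp, fp, tn, fn, accuracy,
#'   sensitivity, specificity, precision, f1` and, when scores are given,
#'   `auc`.
#' @examples
#' compute_metrics(c(1, 1, -1, -1), c(1, -1, -1, -1), c(2, -0.5, -1, -2))
#' @export
compute_metrics <- function(truth, pred, scores = NULL) {
  truth <- coerce_labels(truth, quiet = TRUE)
  pred <- coerce_labels(pred, quiet = TRUE)
  if (length(truth) != length(pred)) abort("`truth` and `pred` lengths differ")
  if (length(unique(truth)) < 2L) {
    abort("AUC undefined: both classes must be present in `truth`")
  }
  tp <- sum(truth == 1 & pred == 1)
  fp <- sum(truth == -1 & pred == 1)
  tn <- sum(truth == -1 & pred == -1)
  fn <- sum(truth == 1 & pred == -1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- tp / (tp + fn)
  out <- tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = (tp + tn) / length(truth),
    sensitivity = recall,
    specificity = tn / (tn + fp),
    precision = precision,
    f1 = if (!is.na(precision) && precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else 0
  )
  if (!is.null(scores)) {
    if (length(scores) != length(truth)) abort("`scores` length differs from `truth`")
    out$auc <- auc_trapezoid(roc_points(truth, scores))
  }
  out
}

#' Empirical ROC curve
#'
#' One operating point per distinct score threshold (ties collapse into a
#' single point), plus the (0, 0) and (1, 1) anchors.
#'
#' @inheritParams compute_metrics
#' @return a tibble with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(truth, scores) {
  truth <- coerce_labels(truth, quiet = TRUE)
  if (length(unique(truth)) < 2L) abort("AUC undefined: single-class truth")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- truth[ord]
  np <- sum(y == 1)
  nn <- sum(y == -1)
  tp <- cumsum(y == 1)
  fp <- cumsum(y == -1)
  last <- c(s[-1] != s[-length(s)], TRUE)   # keep last index of each tie group
  tibble::tibble(
    threshold = c(Inf, s[last]),
    fpr = c(0, fp[last] / nn),
    tpr = c(0, tp[last] / np)
  )
}

auc_trapezoid <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + roc$tpr[-1]) / 2)
}

#' Cross-validated evaluation of the full pipeline
#'
#' Stratified `folds`-fold outer cross-validation. Within each fold, every
#' (modality, timepoint) cell is standardized on the training subjects,
#' hypergraph Laplacians are built on the training subjects, the solver is
#' fitted, features with non-zero weight are selected, the kernel mixing
#' weights are tuned by inner stratified cross-validation on the training
#' set, and the resulting multi-kernel SVM is scored on the held-out
#' subjects. Test data only ever enter through the frozen training
#' statistics, so there is no leakage.
#'
#' @param data a [cohort()].
#' @param params an [hf_params()].
#' @param folds number of outer folds (default 10).
#' @param seed integer seed; fold assignment (outer and inner) and nothing
#'   else depends on it.
#' @param weight_grid_step simplex resolution for the kernel-weight search.
#' @param C SVM cost (default 1).
#' @param inner_folds folds for the kernel-weight search (default 10).
#' @param roi_names optional ROI name map (see [read_roi_names()]) used to
#'   label features in the stability report.
#' @param top_k how many features to keep in the ranked stability list.
#' @return an object of class `hf_cv`: list with `pooled` (one-row metric
#'   tibble from the summed confusion matrix and pooled scores), `by_fold`
#'   (per-fold metrics), `predictions`, `roc` (pooled ROC points),
#'   `stability` (per-(modality, feature) selection counts across folds,
#'   ranked), `selections`, `mix_weights` (per fold) and the run settings.
#' @export
hf_cv <- function(data, params = hf_params(), folds = 10, seed = 1,
                  weight_grid_step = 0.1, C = 1, inner_folds = 10,
                  roi_names = NULL, top_k = 10) {
  stopifnot(inherits(data, "cohort"))
  counts <- table(data$labels)
  if (min(counts) < folds) {
    abort(sprintf("too few subjects: %d in the smallest class for %d folds",
                  min(counts), folds))
  }
  assignment <- stratified_folds(data$labels, folds, seed)
  fold_ids <- sort(unique(assignment))

  predictions <- vector("list", length(fold_ids))
  selections <- vector("list", length(fold_ids))
  weights <- vector("list", length(fold_ids))
  for (f in fold_ids) {
    res <- run_fold(data, params, test_idx = which(assignment == f),
                    weight_grid_step = weight_grid_step, C = C,
                    inner_folds = inner_folds,
                    inner_seed = fold_seed(seed, f))
    predictions[[f]] <- dplyr::mutate(res$predictions, fold = f, .before = 1)
    selections[[f]] <- res$selection
    weights[[f]] <- res$mix_weights
  }
  predictions <- dplyr::bind_rows(predictions)

  by_fold <- predictions |>
    dplyr::group_by(.data$fold) |>
    dplyr::group_modify(function(df, key) {
      m <- compute_metrics(df$truth, df$pred)
      # per-fold AUC where the fold holds both classes
      m$auc <- if (length(unique(df$truth)) == 2L) {
        auc_trapezoid(roc_points(df$truth, df$score))
      } else NA_real_
      m
    }) |>
    dplyr::ungroup()
  pooled <- compute_metrics(predictions$truth, predictions$pred,
                            predictions$score)

  structure(
    list(pooled = pooled, by_fold = by_fold, predictions = predictions,
         roc = roc_points(predictions$truth, predictions$score),
         stability = stability_table(selections, data, roi_names, top_k),
         selections = selections,
         mix_weights = weights,
         folds = assignment, params = params, seed = seed,
         settings = list(weight_grid_step = weight_grid_step, C = C,
                         inner_folds = inner_folds, top_k = top_k)),
    class = "hf_cv"
  )
}

# Derived seed for fold-level randomness; kept well below 2^31.
fold_seed <- function(seed, fold) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(fold)
}

run_fold <- function(data, params, test_idx, weight_grid_step, C,
                     inner_folds, inner_seed) {
  train_idx <- setdiff(seq_len(n_subjects(data)), test_idx)
  train <- subset_cohort(data, subjects = train_idx)
  test <- subset_cohort(data, subjects = test_idx)

  std <- standardize_cohort(train)
  train_std <- std$cohort
  test_std <- standardize_cohort(test, stats = std$stats)$cohort

  fit <- hf_fit(train_std, params, standardize = FALSE)
  sel <- hf_select(fit)
  train_vec <- modality_vectors(train_std, sel)
  test_vec <- modality_vectors(test_std, sel)

  clf <- mk_svm(train_vec, train_std$labels,
                weight_grid_step = weight_grid_step, C = C,
                inner_folds = inner_folds, seed = inner_seed)
  test_grams <- lapply(names(train_vec), function(mod) {
    linear_gram(train_vec[[mod]], test_vec[[mod]])
  })
  names(test_grams) <- names(train_vec)
  scored <- predict(clf, test_grams)

  list(
    predictions = tibble::tibble(
      subject = test$subject_ids, truth = test$labels,
      pred = scored$.pred, score = scored$.score),
    selection = sel,
    mix_weights = clf$mix_weights
  )
}

stability_table <- function(selections, data, roi_names, top_k) {
  counts <- dplyr::bind_rows(lapply(selections, function(sel) {
    dplyr::distinct(sel$by_cell, .data$modality, .data$feature)
  })) |>
    dplyr::count(.data$modality, .data$feature, name = "count") |>
    dplyr::arrange(.data$modality, dplyr::desc(.data$count), .data$feature)
  counts$feature_name <- data$feature_names[counts$feature]
  if (!is.null(roi_names)) {
    counts$roi <- roi_names$name[match(counts$feature, roi_names$index)]
  }
  counts |>
    dplyr::group_by(.data$modality) |>
    dplyr::slice_head(n = top_k) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
}

#' @export
print.hf_cv <- function(x, ...) {
  p <- x$pooled
  cat(sprintf(
    "<hf_cv> %d folds, %d subjects\n  pooled: ACC %.2f%%  SEN %.2f%%  SPE %.2f%%  F1 %.2f%%  AUC %.4f\n",
    length(unique(x$folds)), length(x$folds),
    100 * p$accuracy, 100 * p$sensitivity, 100 * p$specificity,
    100 * p$f1, p$auc))
  invisible(x)
}

#' Ablation of the regularization terms
#'
#' `hf_ablation()` reruns [hf_cv()] with the named regularization weights
#' forced to zero. `hf_ablation_table()` runs the four canonical
#' configurations -- no regularization, group sparsity only, group
#' sparsity + hypergraph, and the full model -- and returns one metric row
#' per configuration.
#'
#' @param data a [cohort()].
#' @param params an [hf_params()] holding the full-model weights.
#' @param which character subset of `c("beta", "lambda", "mu")` to zero.
#' @param ... passed on to [hf_cv()] (`folds`, `seed`, ...).
#' @return `hf_ablation()`: an `hf_cv`. `hf_ablation_table()`: a tibble
#'   with one row per configuration.
#' @export
hf_ablation <- function(data, params, which = character(), ...) {
  bad <- setdiff(which, c("beta", "lambda", "mu"))
  if (length(bad)) abort(sprintf("unknown regularization term(s): %s",
                                 paste(bad, collapse = ", ")))
  for (nm in which) params[[nm]] <- 0
  hf_cv(data, params, ...)
}

#' @rdname hf_ablation
#' @export
hf_ablation_table <- function(data, params, ...) {
  configs <- list(
    none = c("beta", "lambda", "mu"),
    group_sparsity = c("lambda", "mu"),
    group_and_hypergraph = "mu",
    full = character()
  )
  rows <- purrr::imap(configs, function(zeroed, nm) {
    cv <- hf_ablation(data, params, which = zeroed, ...)
    dplyr::mutate(cv$pooled, configuration = nm, .before = 1)
  })
  dplyr::bind_rows(rows)
}

#' Canonical hyperparameter grids
#'
#' The default regularization grid (10 values spanning 1e-4 to 5) and the
#' default KNN-size grid (8 values from 3 to 30) used by [hf_sweep()].
#'
#' @return a numeric vector.
#' @export
default_reg_grid <- function() {
  c(0.0001, 0.0005, 0.001, 0.005, 0.01, 0.05, 0.1, 0.5, 1, 5)
}

#' @rdname default_reg_grid
#' @export
default_k_grid <- function() c(3, 5, 7, 10, 15, 20, 25, 30)

#' Exhaustive hyperparameter sweep
#'
#' Evaluates [hf_cv()] on every point of the Cartesian product of the
#' supplied grids and tabulates the pooled metrics. The same seed (hence
#' the same fold assignment) is used at every grid point, so rows are
#' directly comparable. Beware: the full default product is large; fix
#' some grids to a single value for targeted sweeps.
#'
#' @param data a [cohort()].
#' @param params an [hf_params()] providing non-swept settings.
#' @param grid named list with any of `beta`, `lambda`, `mu`, `k`; each a
#'   vector of candidate values. Omitted entries default to the single
#'   value in `params`.
#' @param ... passed on to [hf_cv()].
#' @return a tibble with one row per grid point: the hyperparameters plus
#'   pooled accuracy and the other metrics, and the fold-to-fold accuracy
#'   SD (`accuracy_sd`).
#' @export
hf_sweep <- function(data, params = hf_params(), grid = list(), ...) {
  full <- list(beta = grid$beta %||% params$beta,
               lambda = grid$lambda %||% params$lambda,
               mu = grid$mu %||% params$mu,
               k = grid$k %||% params$k)
  if (any(lengths(full) == 0L)) abort("grids must be non-empty")
  points <- expand.grid(beta = full$beta, lambda = full$lambda,
                        mu = full$mu, k = full$k,
                        KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(points)), function(i) {
    p <- params
    p$beta <- points$beta[i]
    p$lambda <- points$lambda[i]
    p$mu <- points$mu[i]
    p$k <- as.integer(points$k[i])
    cv <- hf_cv(data, p, ...)
    dplyr::bind_cols(
      tibble::as_tibble(points[i, , drop = FALSE]),
      cv$pooled,
      tibble::tibble(accuracy_sd = stats::sd(cv$by_fold$accuracy))
    )
  })
  dplyr::bind_rows(rows)
}
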