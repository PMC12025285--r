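#' Tidy a fitted feature-selection model
#'
#' One row per (modality, feature, timepoint) coefficient.
#'
#' @param x an [hf_fit()].
#' @param ... unused.
#' @return a tibble with columns `modality`, `feature`, `feature_name`,
#'   `timepoint`, `weight`, `selected`.
#' @export
tidy.hf_fit <- function(x, ...) {
  rows <- purrr::imap(x$W, function(Wm, mod) {
    tibble::tibble(
      modality = mod,
      feature = rep(seq_len(nrow(Wm)), times = ncol(Wm)),
      feature_name = rep(x$feature_names, times = ncol(Wm)),
      timepoint = rep(x$timepoint_names, each = nrow(Wm)),
      weight = as.vector(Wm)
    )
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(selected = abs(.data$weight) > x$params$threshold)
}

#' @rdname tidy.hf_fit
#' @export
glance.hf_fit <- function(x, ...) {
  sel <- hf_select(x)
  tibble::tibble(
    iterations = x$iterations,
    converged = x$converged,
    objective = x$objective_trace[length(x$objective_trace)],
    n_selected = sum(lengths(sel$by_modality)),
    beta = x$params$beta, lambda = x$params$lambda, mu = x$params$mu,
    k = x$params$k
  )
}

#' Tidy a cross-validated run
#'
#' @param x an [hf_cv()].
#' @param ... unused.
#' @return `tidy()`: the per-fold metric tibble; `glance()`: the one-row
#'   pooled metric tibble.
#' @export
tidy.hf_cv <- function(x, ...) x$by_fold

#' @rdname tidy.hf_cv
#' @export
glance.hf_cv <- function(x, ...) x$pooled

#' Tidy a multi-kernel SVM
#'
#' @param x an [mk_svm()].
#' @param ... unused.
#' @return `tidy()`: the mixing-weight search table (one row per simplex
#'   candidate with its inner-CV accuracy); `glance()`: one row with the
#'   winning weights and accuracy.
#' @export
tidy.mk_svm <- function(x, ...) {
  tidyr::unnest_wider(x$search, "weights", names_sep = "_")
}

#' @rdname tidy.mk_svm
#' @export
glance.mk_svm <- function(x, ...) {
  tibble::tibble(
    cv_accuracy = x$cv_accuracy,
    n_train = x$n_train,
    !!!stats::setNames(as.list(x$mix_weights),
                       paste0("weight_", x$modalities %||%
                                seq_along(x$mix_weights)))
  )
}
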