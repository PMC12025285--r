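#' Longitudinal multimodal cohort container
#'
#' A `cohort` bundles one subjects-by-features matrix per (modality, time
#' point) cell together with a single shared binary diagnostic label vector.
#' All cells must refer to the same subjects in the same order and share the
#' same feature dimension. Labels are stored as `-1`/`+1` and the diagnosis
#' is treated as time-invariant.
#'
#' @param features a nested list: `features[[m]][[t]]` is the N x d numeric
#'   matrix for modality `m` at time point `t`. All cells must have
#'   identical dimensions.
#' @param labels numeric vector of length N with entries in `{-1, 1}` (or
#'   any two distinct values, which are mapped onto `{-1, 1}`; see
#'   [coerce_labels()]).
#' @param modality_names,timepoint_names,feature_names optional character
#'   labels; sensible defaults (`"mod1"`, `"t1"`, `"f1"`, ...) are generated
#'   when omitted.
#' @param subject_ids optional character vector of subject identifiers.
#'
#' @return an object of class `cohort` with elements `features`, `labels`,
#'   `modality_names`, `timepoint_names`, `feature_names`, `subject_ids`.
#' @examples
#' x <- matrix(rnorm(40), 10, 4)
#' co <- cohort(list(list(x, x)), labels = rep(c(-1, 1), 5))
#' n_subjects(co)
#' @export
cohort <- function(features, labels, modality_names = NULL,
                   timepoint_names = NULL, feature_names = NULL,
                   subject_ids = NULL) {
  if (!is.list(features) || length(features) == 0L ||
      !all(vapply(features, is.list, logical(1)))) {
    abort("`features` must be a non-empty nested list: features[[modality]][[timepoint]].")
  }
  M <- length(features)
  Ts <- unique(vapply(features, length, integer(1)))
  if (length(Ts) != 1L || Ts == 0L) {
    abort("every modality must supply the same, non-zero number of time points")
  }
  T_ <- Ts
  features <- lapply(features, function(cells) lapply(cells, as.matrix))
  dims <- unique(do.call(rbind, lapply(features, function(cells) {
    t(vapply(cells, dim, integer(2)))
  })))
  if (nrow(dims) != 1L) {
    abort("dimension mismatch: all (modality, timepoint) cells must be N x d with identical N and d")
  }
  N <- dims[1, 1]
  d <- dims[1, 2]
  for (m in seq_len(M)) {
    for (t in seq_len(T_)) {
      if (!all(is.finite(features[[m]][[t]]))) {
        abort(sprintf("non-finite feature values in modality %d, timepoint %d", m, t))
      }
    }
  }
  labels <- coerce_labels(labels, quiet = TRUE)
  if (length(labels) != N) {
    abort(sprintf("dimension mismatch: %d labels for %d subjects", length(labels), N))
  }
  if (length(unique(labels)) < 2L) {
    abort("labels must contain both classes")
  }
  modality_names <- modality_names %||% paste0("mod", seq_len(M))
  timepoint_names <- timepoint_names %||% paste0("t", seq_len(T_))
  feature_names <- feature_names %||% paste0("f", seq_len(d))
  subject_ids <- subject_ids %||% sprintf("S%03d", seq_len(N))
  stopifnot(length(modality_names) == M, length(timepoint_names) == T_,
            length(feature_names) == d, length(subject_ids) == N)
  names(features) <- modality_names
  for (m in seq_len(M)) {
    names(features[[m]]) <- timepoint_names
    for (t in seq_len(T_)) {
      dimnames(features[[m]][[t]]) <- list(subject_ids, feature_names)
    }
  }
  structure(
    list(features = features, labels = labels,
         modality_names = modality_names, timepoint_names = timepoint_names,
         feature_names = feature_names, subject_ids = subject_ids),
    class = "cohort"
  )
}

#' Map a label vector onto -1/+1
#'
#' Labels already in `{-1, 1}` pass through unchanged. Any other pair of
#' distinct values is mapped with the smaller (by sort order) value to `-1`
#' and the larger to `+1`, and the mapping is reported with a message.
#'
#' @param labels vector with exactly two distinct values.
#' @param quiet suppress the mapping message.
#' @return numeric vector of -1/+1.
#' @export
coerce_labels <- function(labels, quiet = FALSE) {
  if (is.factor(labels)) labels <- as.character(labels)
  vals <- sort(unique(labels))
  if (length(vals) > 2L) {
    abort(sprintf("non-binary labels: found %d distinct values", length(vals)))
  }
  if (is.numeric(labels) && setequal(vals, c(-1, 1))) {
    return(as.numeric(labels))
  }
  if (length(vals) < 2L) {
    # single-class vectors are allowed here; cohort() rejects them later
    return(ifelse(labels == vals[1], -1, 1) * 1)
  }
  out <- ifelse(labels == vals[2], 1, -1)
  if (!quiet) {
    inform(sprintf("labels mapped: %s -> -1, %s -> +1", vals[1], vals[2]))
  }
  as.numeric(out)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %d subjects x %d features, %d modalities (%s) x %d time points (%s)\n",
    n_subjects(x), n_features(x), n_modalities(x),
    paste(x$modality_names, collapse = ", "), n_timepoints(x),
    paste(x$timepoint_names, collapse = ", ")
  ))
  tab <- table(factor(x$labels, levels = c(-1, 1)))
  cat(sprintf("  labels: %d x -1, %d x +1\n", tab[["-1"]], tab[["1"]]))
  invisible(x)
}

#' Cohort dimensions
#'
#' @param x a [cohort()].
#' @return an integer scalar.
#' @export
n_subjects <- function(x) length(x$labels)

#' @rdname n_subjects
#' @export
n_features <- function(x) length(x$feature_names)

#' @rdname n_subjects
#' @export
n_modalities <- function(x) length(x$features)

#' @rdname n_subjects
#' @export
n_timepoints <- function(x) length(x$timepoint_names)

#' Subset a cohort by subjects, modalities or time points
#'
#' @param x a [cohort()].
#' @param subjects integer or logical index over subjects.
#' @param modalities integer index or names of modalities to keep.
#' @param timepoints integer index or names of time points to keep.
#' @return a new [cohort()] (planted ground truth, if attached, is carried
#'   over and restricted to the kept modalities).
#' @export
subset_cohort <- function(x, subjects = NULL, modalities = NULL,
                          timepoints = NULL) {
  stopifnot(inherits(x, "cohort"))
  subjects <- subjects %||% seq_len(n_subjects(x))
  if (is.logical(subjects)) subjects <- which(subjects)
  modalities <- modalities %||% seq_len(n_modalities(x))
  if (is.character(modalities)) modalities <- match(modalities, x$modality_names)
  timepoints <- timepoints %||% seq_len(n_timepoints(x))
  if (is.character(timepoints)) timepoints <- match(timepoints, x$timepoint_names)
  feats <- lapply(x$features[modalities], function(cells) {
    lapply(cells[timepoints], function(mat) mat[subjects, , drop = FALSE])
  })
  out <- cohort(feats, x$labels[subjects],
                modality_names = x$modality_names[modalities],
                timepoint_names = x$timepoint_names[timepoints],
                feature_names = x$feature_names,
                subject_ids = x$subject_ids[subjects])
  gt <- attr(x, "ground_truth")
  if (!is.null(gt)) attr(out, "ground_truth") <- gt[modalities]
  out
}

#' Planted informative features of a simulated cohort
#'
#' @param x a cohort produced by [simulate_cohort()].
#' @return a named list, per modality, of planted feature indices, or
#'   `NULL` when the cohort carries no ground truth.
#' @export
ground_truth <- function(x) attr(x, "ground_truth")

#' @export
as_tibble.cohort <- function(x, ...) {
  rows <- purrr::imap(x$features, function(cells, mod) {
    purrr::imap(cells, function(mat, tp) {
      tibble::tibble(
        subject = rep(x$subject_ids, times = ncol(mat)),
        label = rep(x$labels, times = ncol(mat)),
        modality = mod,
        timepoint = tp,
        feature = rep(colnames(mat), each = nrow(mat)),
        value = as.vector(mat)
      )
    })
  })
  dplyr::bind_rows(purrr::flatten(rows))
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

# Center/scale every (m, t) cell on its own (training) statistics.
# Returns list(cohort, centers, scales); `stats` re-applies stored
# statistics to new data (test folds), guaranteeing no leakage.
standardize_cohort <- function(x, stats = NULL) {
  M <- n_modalities(x)
  T_ <- n_timepoints(x)
  centers <- scales <- vector("list", M)
  feats <- x$features
  for (m in seq_len(M)) {
    centers[[m]] <- scales[[m]] <- vector("list", T_)
    for (t in seq_len(T_)) {
      mat <- feats[[m]][[t]]
      if (is.null(stats)) {
        ctr <- colMeans(mat)
        scl <- apply(mat, 2, stats::sd)
        scl[!is.finite(scl) | scl < 1e-12] <- 1
      } else {
        ctr <- stats$centers[[m]][[t]]
        scl <- stats$scales[[m]][[t]]
      }
      feats[[m]][[t]] <- sweep(sweep(mat, 2, ctr, "-"), 2, scl, "/")
      centers[[m]][[t]] <- ctr
      scales[[m]][[t]] <- scl
    }
  }
  out <- x
  out$features <- feats
  list(cohort = out,
       stats = list(centers = centers, scales = scales))
}
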