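#' Concatenate selected features across time points, per modality
#'
#' For each modality, every time point's matrix is restricted to that
#' modality's selected features and the T blocks are concatenated
#' column-wise (time-point order, subject order preserved), yielding one
#' N x (|selection| * T) representation per modality.
#'
#' @param data a [cohort()].
#' @param selection named list of feature-index vectors per modality (e.g.
#'   the `by_modality` element of [hf_select()]), or an `hf_selection`.
#' @return named list of per-modality matrices. Modalities with an empty
#'   selection are dropped; if all are empty an error is raised.
#' @export
modality_vectors <- function(data, selection) {
  stopifnot(inherits(data, "cohort"))
  if (inherits(selection, "hf_selection")) selection <- selection$by_modality
  if (is.null(names(selection))) names(selection) <- data$modality_names[seq_along(selection)]
  if (all(lengths(selection) == 0L)) abort("no features selected")
  keep <- names(selection)[lengths(selection) > 0L]
  out <- lapply(stats::setNames(keep, keep), function(mod) {
    sel <- selection[[mod]]
    blocks <- lapply(data$features[[mod]], function(mat) mat[, sel, drop = FALSE])
    mat <- do.call(cbind, blocks)
    colnames(mat) <- as.vector(t(outer(data$timepoint_names,
                                       data$feature_names[sel],
                                       function(tp, f) paste(f, tp, sep = "_"))))
    mat
  })
  out
}

#' Linear Gram matrix
#'
#' Inner products of the rows of `b` against the rows of `a`:
#' `linear_gram(a)` is the symmetric positive semidefinite train-train
#' Gram; `linear_gram(train, test)` is the test-vs-train matrix used at
#' prediction time.
#'
#' @param a numeric Na x p matrix (training representation).
#' @param b numeric Nb x p matrix (defaults to `a`).
#' @return Nb x Na matrix of inner products.
#' @export
linear_gram <- function(a, b = a) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  if (ncol(a) != ncol(b)) abort("dimension mismatch: feature counts differ")
  out <- tcrossprod(b, a)
  if (identical(dim(a), dim(b)) && isTRUE(all.equal(a, b))) {
    out <- (out + t(out)) / 2
  }
  out
}

#' Convex combination of per-modality Gram matrices
#'
#' @param grams list of equally-sized Gram matrices.
#' @param weights numeric mixing weights on the simplex (non-negative,
#'   summing to one within 1e-9).
#' @return the mixed Gram `sum_m weights[m] * grams[[m]]`.
#' @export
combine_kernels <- function(grams, weights) {
  if (length(grams) != length(weights)) {
    abort("one mixing weight per Gram matrix required")
  }
  if (any(weights < -1e-12) || abs(sum(weights) - 1) > 1e-9) {
    abort("mixing weights off the simplex")
  }
  Reduce(`+`, Map(`*`, grams, weights))
}

#' Candidate mixing-weight vectors on the simplex
#'
#' All M-vectors with non-negative entries on a grid of resolution `step`
#' that sum to one, in lexicographic order (first coordinate descending
#' from 1). For M = 2 and step 0.1 this gives the 11 candidates
#' (1, 0), (0.9, 0.1), ..., (0, 1).
#'
#' @param m number of modalities.
#' @param step grid resolution in (0, 1].
#' @return a matrix with one candidate per row.
#' @export
simplex_grid <- function(m, step = 0.1) {
  if (step <= 0 || step > 1) abort("`step` must lie in (0, 1]")
  levels <- round(1 / step)
  rec <- function(m, units) {
    if (m == 1L) return(matrix(units, 1, 1))
    do.call(rbind, lapply(units:0, function(u) {
      rest <- rec(m - 1L, units - u)
      cbind(u, rest)
    }))
  }
  grid <- rec(as.integer(m), levels) / levels
  dimnames(grid) <- NULL
  grid
}

#' Train a multi-kernel SVM with grid-searched mixing weights
#'
#' Builds one linear Gram matrix per modality from the concatenated
#' selected features, grid-searches the simplex mixing weights at
#' resolution `weight_grid_step` by stratified `inner_folds`-fold
#' cross-validated accuracy on the training set only (ties broken toward
#' the first grid candidate), and refits a C-SVM with the precomputed
#' mixed kernel at the winning weights. The SVM cost is left at its
#' default `C = 1` unless overridden.
#'
#' @param vectors named list of per-modality N x p_m training matrices
#'   (from [modality_vectors()]).
#' @param labels length-N vector of -1/+1 training labels.
#' @param weight_grid_step simplex grid resolution (default 0.1).
#' @param C SVM cost parameter (default 1).
#' @param inner_folds folds of the inner cross-validation (default 10;
#'   reduced automatically if a class has fewer members).
#' @param seed seed fixing the inner fold assignment.
#' @return an object of class `mk_svm` with the fitted kernlab model, the
#'   winning `mix_weights`, the inner-CV `search` table and bookkeeping
#'   needed for prediction.
#' @export
mk_svm <- function(vectors, labels, weight_grid_step = 0.1, C = 1,
                   inner_folds = 10, seed = 1) {
  stopifnot(is.list(vectors), length(vectors) >= 1L)
  labels <- coerce_labels(labels, quiet = TRUE)
  n <- length(labels)
  if (any(vapply(vectors, nrow, integer(1)) != n)) {
    abort("dimension mismatch between vectors and labels")
  }
  counts <- table(factor(labels, levels = c(-1, 1)))
  if (any(counts < 2)) abort("need at least 2 subjects per class in training data")

  grams <- lapply(vectors, linear_gram)
  M <- length(grams)
  grid <- simplex_grid(M, weight_grid_step)
  folds <- stratified_folds(labels, min(inner_folds, min(counts)), seed)

  cv_acc <- apply(grid, 1, function(wts) {
    K <- combine_kernels(grams, wts)
    correct <- 0L
    for (f in sort(unique(folds))) {
      te <- which(folds == f)
      tr <- which(folds != f)
      if (length(unique(labels[tr])) < 2L) abort("single-class training fold")
      model <- fit_ksvm(K[tr, tr, drop = FALSE], labels[tr], C)
      pred <- predict_ksvm(model, K[te, tr, drop = FALSE])
      correct <- correct + sum(pred$label == labels[te])
    }
    correct / n
  })
  best <- which.max(cv_acc)  # ties -> first (lexicographically largest w1)
  mix_weights <- grid[best, ]
  K <- combine_kernels(grams, mix_weights)
  model <- fit_ksvm(K, labels, C)

  structure(
    list(model = model, mix_weights = stats::setNames(mix_weights, names(vectors)),
         modalities = names(vectors), n_train = n, C = C,
         cv_accuracy = cv_acc[best],
         search = tibble::tibble(
           candidate = seq_len(nrow(grid)),
           weights = lapply(seq_len(nrow(grid)), function(i) grid[i, ]),
           cv_accuracy = as.numeric(cv_acc)
         )),
    class = "mk_svm"
  )
}

#' @export
print.mk_svm <- function(x, ...) {
  cat(sprintf("<mk_svm> %d training subjects; mix weights (%s); inner-CV accuracy %.3f\n",
              x$n_train,
              paste(sprintf("%s=%.2f", x$modalities, x$mix_weights), collapse = ", "),
              x$cv_accuracy))
  invisible(x)
}

#' Predict from a multi-kernel SVM
#'
#' @param object an [mk_svm()].
#' @param grams list of per-modality test-vs-train Gram matrices
#'   (Nt x Ntrain, same modality and training-subject order as at fit
#'   time), or a single precomputed mixed Gram matrix.
#' @param ... unused.
#' @return a tibble with `.pred` (-1/+1) and `.score` (decision value,
#'   larger means more +1-like).
#' @export
predict.mk_svm <- function(object, grams, ...) {
  K <- if (is.list(grams)) combine_kernels(grams, object$mix_weights) else grams
  K <- as.matrix(K)
  if (ncol(K) != object$n_train) {
    abort(sprintf("dimension mismatch: Gram has %d columns, expected %d training subjects",
                  ncol(K), object$n_train))
  }
  out <- predict_ksvm(object$model, K)
  tibble::tibble(.pred = out$label, .score = out$score)
}

# -- kernlab plumbing ---------------------------------------------------

# Fit a C-SVM on a precomputed train-train Gram. The PSD Gram is
# factorized as K = Z Z' (truncated eigendecomposition) and the SVM is
# trained on Z with an explicit linear kernel, which yields exactly the
# same dual solution as SMO on the precomputed matrix but avoids kernlab's
# slow element-wise "matrix" kernel path. Test rows of a test-vs-train
# Gram are mapped into the same factor space by Kt V D^(-1/2); components
# of a test point outside the training span are orthogonal to every
# support vector, so decisions are unchanged. The decision-value
# orientation is recorded so that larger scores always mean "more
# +1-like".
fit_ksvm <- function(K, labels, C) {
  y <- factor(labels, levels = c(-1, 1))
  eig <- eigen((K + t(K)) / 2, symmetric = TRUE)
  keep <- eig$values > max(eig$values[1], 0) * 1e-10
  if (!any(keep)) abort("Gram matrix is numerically zero")
  V <- eig$vectors[, keep, drop = FALSE]
  sq <- sqrt(eig$values[keep])
  Z <- sweep(V, 2, sq, "*")
  proj <- sweep(V, 2, sq, "/")   # maps Gram rows onto factor coordinates
  model <- kernlab::ksvm(Z, y, kernel = "vanilladot", kpar = list(),
                         C = C, type = "C-svc", scaled = FALSE)
  dec <- kernlab::predict(model, Z, type = "decision")[, 1]
  sgn <- if (mean(dec[labels == 1]) >= mean(dec[labels == -1])) 1 else -1
  list(model = model, proj = proj, sign = sgn)
}

predict_ksvm <- function(fitted, K) {
  Zt <- K %*% fitted$proj
  lab <- as.numeric(as.character(kernlab::predict(fitted$model, Zt)))
  score <- fitted$sign * kernlab::predict(fitted$model, Zt, type = "decision")[, 1]
  list(label = lab, score = score)
}

# Stratified fold assignment: within each class, subjects are shuffled
# under `seed` and dealt round-robin into `k` folds.
stratified_folds <- function(labels, k, seed) {
  k <- max(2L, as.integer(k))
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}
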