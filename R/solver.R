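#' Hyperparameters of the longitudinal feature-selection objective
#'
#' The fitted objective is, with `X[m,t]` the N x d cell matrices, `w[m,t]`
#' the d-vector of coefficients of task (m, t) and `L[m,t]` the per-cell
#' hypergraph Laplacians,
#'
#' \deqn{\tfrac12 \sum_{m,t} \|Y - X_{mt} w_{mt}\|_2^2
#'   + \beta \|W\|_{2,1}
#'   + \lambda \sum_{m,t} (X_{mt} w_{mt})^\top L_{mt} (X_{mt} w_{mt})
#'   + \mu \sum_m \sum_{t=1}^{T-1} \|w_{m,t+1} - w_{mt}\|_1}
#'
#' where the l2,1 norm sums the Euclidean norms of the rows of the stacked
#' (d m) x T coefficient matrix, one group per (feature, modality) row
#' spanning the T time points.
#'
#' @param beta group-sparsity weight (>= 0): drives whole (feature,
#'   modality) rows to zero, selecting the same features at every visit.
#' @param lambda hypergraph-regularization weight (>= 0): penalizes fitted
#'   scores that disagree across subjects joined by a hyperedge.
#' @param mu fused-lasso weight (>= 0): an l1 penalty on differences of
#'   adjacent time points' coefficients, enforcing temporal smoothness.
#' @param k KNN size used to build the per-cell hypergraphs.
#' @param max_iter maximum number of accelerated proximal gradient
#'   iterations.
#' @param tol relative-objective convergence threshold.
#' @param step_init initial step size for the backtracking line search.
#' @param step_shrink backtracking shrink factor in (0, 1).
#' @param threshold magnitude below which a fitted coefficient counts as
#'   zero when selecting features.
#' @return an object of class `hf_params`.
#' @export
hf_params <- function(beta = 1, lambda = 0.01, mu = 0.5, k = 7,
                      max_iter = 1000, tol = 1e-5, step_init = 1,
                      step_shrink = 0.5, threshold = 1e-8) {
  if (beta < 0 || lambda < 0 || mu < 0) {
    abort("regularization weights beta, lambda, mu must be >= 0")
  }
  if (step_shrink <= 0 || step_shrink >= 1) abort("`step_shrink` must be in (0, 1)")
  if (tol <= 0) abort("`tol` must be > 0")
  if (step_init <= 0) abort("`step_init` must be > 0")
  structure(
    list(beta = beta, lambda = lambda, mu = mu, k = as.integer(k),
         max_iter = as.integer(max_iter), tol = tol, step_init = step_init,
         step_shrink = step_shrink, threshold = threshold),
    class = "hf_params"
  )
}

#' @export
print.hf_params <- function(x, ...) {
  cat(sprintf(
    "<hf_params> beta=%g lambda=%g mu=%g k=%d (max_iter=%d, tol=%g)\n",
    x$beta, x$lambda, x$mu, x$k, x$max_iter, x$tol))
  invisible(x)
}

# A weight tensor is a plain list of d x T matrices, one per modality.
zero_weights <- function(data) {
  d <- n_features(data)
  T_ <- n_timepoints(data)
  stats::setNames(
    replicate(n_modalities(data), matrix(0, d, T_), simplify = FALSE),
    data$modality_names
  )
}

check_weights <- function(W, data) {
  if (!is.list(W) || length(W) != n_modalities(data)) {
    abort("weight tensor must be a list with one d x T matrix per modality")
  }
  for (Wm in W) {
    if (!is.matrix(Wm) || nrow(Wm) != n_features(data) ||
        ncol(Wm) != n_timepoints(data)) {
      abort("dimension mismatch between weight tensor and cohort")
    }
  }
  invisible(TRUE)
}

#' Build the per-cell hypergraph Laplacians of a cohort
#'
#' One KNN hypergraph (see [knn_hypergraph()]) is built per (modality, time
#' point) cell from that cell's feature matrix, and its normalized
#' Laplacian is returned.
#'
#' @param data a [cohort()].
#' @param k KNN size.
#' @param scale z-score features before the distance computation.
#' @return nested list `laps[[m]][[t]]` of [hypergraph_laplacian()] objects.
#' @export
cohort_laplacians <- function(data, k, scale = TRUE) {
  lapply(data$features, function(cells) {
    lapply(cells, function(mat) hypergraph_laplacian(knn_hypergraph(mat, k, scale = scale)))
  })
}

# Precompute per-cell quantities so that the smooth part and its gradient
# are d x d operations:
#   h(W)   = sum_cells [ 0.5 w'Gw - b'w + c ],  G = X'X + 2 lambda X'LX,
#   grad_w = G w - b,                           b = X'Y, c = 0.5 ||Y||^2.
precompute_smooth <- function(data, laps, params) {
  Y <- data$labels
  lapply(seq_len(n_modalities(data)), function(m) {
    lapply(seq_len(n_timepoints(data)), function(t) {
      X <- data$features[[m]][[t]]
      G <- crossprod(X)
      if (params$lambda > 0) {
        if (is.null(laps)) abort("hypergraph Laplacians required when lambda > 0")
        G <- G + 2 * params$lambda * crossprod(X, laps[[m]][[t]]$matrix %*% X)
        G <- (G + t(G)) / 2
      }
      list(G = G, b = drop(crossprod(X, Y)), c = 0.5 * sum(Y^2))
    })
  })
}

smooth_value_pre <- function(pre, W) {
  total <- 0
  for (m in seq_along(pre)) {
    for (t in seq_along(pre[[m]])) {
      w <- W[[m]][, t]
      cell <- pre[[m]][[t]]
      total <- total + 0.5 * drop(crossprod(w, cell$G %*% w)) -
        sum(cell$b * w) + cell$c
    }
  }
  total
}

smooth_grad_pre <- function(pre, W) {
  lapply(seq_along(pre), function(m) {
    g <- W[[m]]
    for (t in seq_along(pre[[m]])) {
      cell <- pre[[m]][[t]]
      g[, t] <- drop(cell$G %*% W[[m]][, t]) - cell$b
    }
    g
  })
}

nonsmooth_value <- function(W, params) {
  total <- 0
  for (Wm in W) {
    total <- total + params$beta * sum(sqrt(rowSums(Wm^2)))
    if (ncol(Wm) > 1L) {
      total <- total + params$mu *
        sum(abs(Wm[, -1, drop = FALSE] - Wm[, -ncol(Wm), drop = FALSE]))
    }
  }
  total
}

#' Objective value of the longitudinal feature-selection problem
#'
#' @param data a [cohort()] (typically standardized training data).
#' @param laps per-cell Laplacians from [cohort_laplacians()]; may be
#'   `NULL` when `params$lambda == 0`.
#' @param W weight tensor: list of d x T matrices, one per modality.
#' @param params an [hf_params()].
#' @return the scalar objective value.
#' @export
hf_objective <- function(data, laps, W, params) {
  check_weights(W, data)
  pre <- precompute_smooth(data, laps, params)
  smooth_value_pre(pre, W) + nonsmooth_value(W, params)
}

#' Gradient of the smooth part of the objective
#'
#' The smooth part is the squared loss plus the hypergraph quadratic
#' penalty; its gradient block for task (m, t) is
#' `X'(Xw - Y) + 2 lambda X'LXw`.
#'
#' @inheritParams hf_objective
#' @return a weight-tensor-shaped gradient (list of d x T matrices).
#' @export
hf_gradient <- function(data, laps, W, params) {
  check_weights(W, data)
  pre <- precompute_smooth(data, laps, params)
  g <- smooth_grad_pre(pre, W)
  names(g) <- names(W)
  g
}

#' One-dimensional fused-lasso signal approximator
#'
#' Solves `min_x 0.5 ||x - y||^2 + lam * sum |x_{t+1} - x_t|` exactly by a
#' direct (non-iterative) taut-string sweep.
#'
#' @param y numeric vector.
#' @param lam non-negative penalty.
#' @return the minimizer, a vector like `y`.
#' @export
fused_lasso_1d <- function(y, lam) {
  if (lam < 0) abort("`lam` must be >= 0")
  .tv1d(as.numeric(y), lam)
}

#' Proximal operator of the non-smooth penalty
#'
#' Computes `argmin_W 0.5 ||W - V||_F^2 + step * g(W)` for
#' `g(W) = beta ||W||_{2,1} + mu * sum_m sum_t ||w_{m,t+1} - w_{mt}||_1`.
#' The composite prox decomposes exactly row by row: first the 1-D
#' fused-lasso signal approximation across the T entries with penalty
#' `step * mu`, then group soft-thresholding of the whole row by
#' `max(0, 1 - step * beta / ||row||_2)`.
#'
#' @param V weight-tensor-shaped point (list of d x T matrices).
#' @param step positive step size.
#' @param params an [hf_params()] supplying `beta` and `mu`.
#' @return the proximal point, same shape as `V`.
#' @export
hf_prox <- function(V, step, params) {
  if (step <= 0) abort("`step` must be > 0")
  lapply(V, function(Vm) {
    out <- .tv1d_rows(Vm, step * params$mu)
    rn <- sqrt(rowSums(out^2))
    shrink <- ifelse(rn > 0, pmax(0, 1 - step * params$beta / rn), 0)
    out * shrink
  })
}

#' Fit the longitudinal multi-task feature-selection model
#'
#' Minimizes the composite objective (see [hf_params()]) by a monotone
#' accelerated proximal gradient method: at each iteration a search point
#' `S = W_i + Delta_i (W_i - W_{i-1})` is formed with the classical
#' momentum sequence `p_i = (1 + sqrt(1 + 4 p_{i-1}^2)) / 2`,
#' `Delta_i = (p_{i-1} - 1) / p_i`; a gradient step at S is taken with
#' backtracking (step halved until the quadratic model upper-bounds the
#' smooth part) followed by the exact proximal step [hf_prox()]. Whenever
#' the accelerated candidate would increase the objective, the iteration
#' falls back to a plain proximal-gradient step from the current iterate
#' (which is guaranteed to be non-increasing) and momentum is restarted, so
#' the reported objective trace is monotone non-increasing.
#'
#' @param data a [cohort()] of training subjects.
#' @param params an [hf_params()].
#' @param standardize z-score every (modality, timepoint) cell on its own
#'   statistics before fitting (default TRUE). The statistics are stored on
#'   the fit for leakage-free transformation of test data.
#' @param laplacians optional precomputed [cohort_laplacians()]; built
#'   internally (with `params$k`) when `lambda > 0` and not supplied.
#' @return an object of class `hf_fit` with elements `W` (list of d x T
#'   coefficient matrices per modality), `objective_trace`, `iterations`,
#'   `converged`, `params`, `scaling` and the cohort's naming metadata.
#' @examples
#' co <- simulate_cohort(sim_spec(n_per_class = 20, d = 10, n_timepoints = 2,
#'                                n_modalities = 1), seed = 1)
#' fit <- hf_fit(co, hf_params(beta = 5, lambda = 0, mu = 1, max_iter = 100))
#' glance(fit)
#' @export
hf_fit <- function(data, params = hf_params(), standardize = TRUE,
                   laplacians = NULL) {
  stopifnot(inherits(data, "cohort"), inherits(params, "hf_params"))
  scaling <- NULL
  if (isTRUE(standardize)) {
    std <- standardize_cohort(data)
    data <- std$cohort
    scaling <- std$stats
  }
  if (params$lambda > 0 && is.null(laplacians)) {
    # features are already z-scored here when standardize = TRUE
    laplacians <- cohort_laplacians(data, params$k, scale = !standardize)
  }
  pre <- precompute_smooth(data, laplacians, params)

  W <- W_old <- zero_weights(data)
  p_old <- 1
  step <- params$step_init
  obj <- smooth_value_pre(pre, W) + nonsmooth_value(W, params)
  trace <- obj
  converged <- FALSE
  iterations <- 0L

  backtrack <- function(S, step) {
    hS <- smooth_value_pre(pre, S)
    gS <- smooth_grad_pre(pre, S)
    repeat {
      V <- Map(function(Sm, Gm) Sm - step * Gm, S, gS)
      cand <- hf_prox(V, step, params)
      diffs <- Map(`-`, cand, S)
      quad <- hS + sum(vapply(seq_along(diffs), function(m) {
        sum(gS[[m]] * diffs[[m]]) + frob2(diffs[[m]]) / (2 * step)
      }, numeric(1)))
      if (smooth_value_pre(pre, cand) <= quad + 1e-12 * max(1, abs(quad))) {
        return(list(W = cand, step = step))
      }
      step <- step * params$step_shrink
      if (step < 1e-15) return(list(W = cand, step = step))
    }
  }

  for (i in seq_len(params$max_iter)) {
    iterations <- i
    p_new <- (1 + sqrt(1 + 4 * p_old^2)) / 2
    delta <- (p_old - 1) / p_new
    S <- Map(function(Wm, Wo) Wm + delta * (Wm - Wo), W, W_old)
    bt <- backtrack(S, step)
    step <- bt$step
    cand <- bt$W
    obj_cand <- smooth_value_pre(pre, cand) + nonsmooth_value(cand, params)
    if (obj_cand > obj) {
      # monotone safeguard: plain proximal-gradient step from W
      bt <- backtrack(W, step)
      step <- bt$step
      cand <- bt$W
      obj_cand <- smooth_value_pre(pre, cand) + nonsmooth_value(cand, params)
      p_new <- 1
    }
    W_old <- W
    W <- cand
    p_old <- p_new
    rel_change <- abs(obj - obj_cand) / max(1, abs(obj))
    obj <- obj_cand
    trace <- c(trace, obj)
    if (rel_change < params$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf("solver did not converge in %d iterations (tol = %g)",
                 params$max_iter, params$tol))
  }
  names(W) <- data$modality_names
  structure(
    list(W = W, objective_trace = trace, iterations = iterations,
         converged = converged, final_step = step, params = params,
         scaling = scaling,
         modality_names = data$modality_names,
         timepoint_names = data$timepoint_names,
         feature_names = data$feature_names),
    class = "hf_fit"
  )
}

#' @export
print.hf_fit <- function(x, ...) {
  sel <- hf_select(x)
  cat(sprintf(
    "<hf_fit> %d modalities x %d features x %d time points; %d iterations (%s)\n",
    length(x$W), nrow(x$W[[1]]), ncol(x$W[[1]]), x$iterations,
    if (x$converged) "converged" else "not converged"))
  cat(sprintf("  objective %.6g; %d features selected\n",
              x$objective_trace[length(x$objective_trace)],
              sum(lengths(sel$by_modality))))
  invisible(x)
}

#' Selected features of a fitted model
#'
#' Returns the (feature, time point) cells whose coefficient magnitude
#' exceeds `threshold`, together with the per-modality union over time
#' points (the feature sets used downstream for kernel construction).
#'
#' @param fit an [hf_fit()] object, or a raw weight tensor (list of d x T
#'   matrices).
#' @param threshold numerical-zero cut-off; defaults to the fit's
#'   `params$threshold` (1e-8).
#' @return an object of class `hf_selection`: a list with `by_cell` (tibble
#'   of modality, feature, timepoint, weight) and `by_modality` (named list
#'   of sorted feature indices).
#' @export
hf_select <- function(fit, threshold = NULL) {
  if (inherits(fit, "hf_fit")) {
    W <- fit$W
    threshold <- threshold %||% fit$params$threshold
    feature_names <- fit$feature_names
    timepoint_names <- fit$timepoint_names
  } else {
    W <- fit
    threshold <- threshold %||% 1e-8
    feature_names <- paste0("f", seq_len(nrow(W[[1]])))
    timepoint_names <- paste0("t", seq_len(ncol(W[[1]])))
  }
  if (threshold < 0) abort("`threshold` must be >= 0")
  mods <- names(W) %||% paste0("mod", seq_along(W))
  cells <- purrr::imap(W, function(Wm, mod) {
    idx <- which(abs(Wm) > threshold, arr.ind = TRUE)
    tibble::tibble(
      modality = if (nrow(idx)) mod else character(),
      feature = as.integer(idx[, 1]),
      feature_name = feature_names[idx[, 1]],
      timepoint = as.integer(idx[, 2]),
      timepoint_name = timepoint_names[idx[, 2]],
      weight = Wm[idx]
    )
  })
  by_cell <- dplyr::bind_rows(cells)
  by_modality <- lapply(stats::setNames(mods, mods), function(mod) {
    sort(unique(by_cell$feature[by_cell$modality == mod]))
  })
  structure(list(by_cell = by_cell, by_modality = by_modality,
                 threshold = threshold),
            class = "hf_selection")
}

#' @export
print.hf_selection <- function(x, ...) {
  cat(sprintf("<hf_selection> threshold %g; %s\n", x$threshold,
              paste(sprintf("%s: %d features", names(x$by_modality),
                            lengths(x$by_modality)), collapse = ", ")))
  invisible(x)
}
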