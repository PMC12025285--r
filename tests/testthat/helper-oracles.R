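# Independent oracles used across the suite. Each reimplements the quantity
# it checks from first principles (enumeration, scalar loops, generic
# optimization) and never calls the code path under test.

# --- 1-D TV prox: exact solution by KKT enumeration of the dual box QP ----
# min_z 0.5 ||D'z||^2 - z'Dy  s.t. |z| <= lam;  x = y - D'z.
tv_prox_oracle <- function(y, lam) {
  n <- length(y)
  if (n == 1 || lam == 0) return(y)
  D <- diff(diag(n))
  Q <- D %*% t(D)
  c0 <- drop(D %*% y)
  m <- n - 1
  states <- expand.grid(rep(list(c(-1, 0, 1)), m))
  for (r in seq_len(nrow(states))) {
    st <- as.numeric(states[r, ])
    z <- numeric(m)
    bound <- which(st != 0)
    free <- which(st == 0)
    z[bound] <- lam * st[bound]
    if (length(free)) {
      rhs <- c0[free] - Q[free, bound, drop = FALSE] %*% z[bound]
      sol <- tryCatch(solve(Q[free, free, drop = FALSE], rhs),
                      error = function(e) NULL)
      if (is.null(sol)) next
      z[free] <- sol
    }
    if (any(abs(z[free]) > lam + 1e-9)) next
    g <- drop(Q %*% z - c0)
    if (all(abs(g[free]) < 1e-8) && all(g[bound] * st[bound] <= 1e-8)) {
      return(as.numeric(y - t(D) %*% z))
    }
  }
  stop("tv_prox_oracle: no KKT point found")
}

# --- full composite prox: generic smoothed convex optimization ------------
# Solves argmin_W 0.5||W - V||_F^2 + step*(beta * sum row norms +
# mu * sum |adjacent diffs|) by BFGS on a tightly smoothed surrogate.
# Makes no use of the fused-then-group decomposition.
prox_oracle <- function(V, step, beta, mu, eps = 1e-12) {
  lapply(V, function(Vm) {
    d <- nrow(Vm)
    T_ <- ncol(Vm)
    fn <- function(w) {
      W <- matrix(w, d, T_)
      val <- 0.5 * sum((W - Vm)^2) +
        step * beta * sum(sqrt(rowSums(W^2) + eps))
      if (T_ > 1) {
        dif <- W[, -1, drop = FALSE] - W[, -T_, drop = FALSE]
        val <- val + step * mu * sum(sqrt(dif^2 + eps))
      }
      val
    }
    gr <- function(w) {
      W <- matrix(w, d, T_)
      G <- (W - Vm) + step * beta * W / sqrt(rowSums(W^2) + eps)
      if (T_ > 1) {
        dif <- W[, -1, drop = FALSE] - W[, -T_, drop = FALSE]
        sm <- dif / sqrt(dif^2 + eps)
        G[, -1] <- G[, -1] + step * mu * sm
        G[, -T_] <- G[, -T_] - step * mu * sm
      }
      as.vector(G)
    }
    res <- stats::optim(as.vector(Vm), fn, gr, method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-15))
    matrix(res$par, d, T_)
  })
}

# --- objective by scalar loops -------------------------------------------
# Term-by-term expansion of the composite objective with explicit loops;
# laps may be NULL when lambda = 0.
objective_loops <- function(data, laps, W, beta, lambda, mu) {
  Y <- data$labels
  total <- 0
  for (m in seq_along(data$features)) {
    Wm <- W[[m]]
    for (t in seq_along(data$features[[m]])) {
      X <- data$features[[m]][[t]]
      scores <- numeric(nrow(X))
      for (i in seq_len(nrow(X))) {
        s <- 0
        for (j in seq_len(ncol(X))) s <- s + X[i, j] * Wm[j, t]
        scores[i] <- s
      }
      total <- total + 0.5 * sum((Y - scores)^2)
      if (lambda > 0) {
        L <- laps[[m]][[t]]$matrix
        q <- 0
        for (i in seq_len(nrow(L))) {
          for (j in seq_len(ncol(L))) q <- q + scores[i] * L[i, j] * scores[j]
        }
        total <- total + lambda * q
      }
    }
    for (j in seq_len(nrow(Wm))) {
      total <- total + beta * sqrt(sum(Wm[j, ]^2))
    }
    if (ncol(Wm) > 1) {
      for (t in seq_len(ncol(Wm) - 1)) {
        total <- total + mu * sum(abs(Wm[, t + 1] - Wm[, t]))
      }
    }
  }
  total
}

# --- diminishing-step subgradient descent on the full objective -----------
# Generic non-smooth first-order oracle; returns the best objective seen.
subgrad_oracle <- function(data, laps, beta, lambda, mu, n_steps = 20000) {
  M <- length(data$features)
  T_ <- length(data$features[[1]])
  d <- ncol(data$features[[1]][[1]])
  Y <- data$labels
  G <- b <- vector("list", M)
  lip <- 0
  for (m in seq_len(M)) {
    G[[m]] <- b[[m]] <- vector("list", T_)
    for (t in seq_len(T_)) {
      X <- data$features[[m]][[t]]
      Gmt <- crossprod(X)
      if (lambda > 0) {
        Gmt <- Gmt + 2 * lambda * crossprod(X, laps[[m]][[t]]$matrix %*% X)
      }
      G[[m]][[t]] <- (Gmt + t(Gmt)) / 2
      b[[m]][[t]] <- drop(crossprod(X, Y))
      lip <- max(lip, max(abs(eigen(G[[m]][[t]], only.values = TRUE)$values)))
    }
  }
  obj <- function(W) objective_loops_fast(data, laps, W, beta, lambda, mu)
  W <- replicate(M, matrix(0, d, T_), simplify = FALSE)
  best <- obj(W)
  step0 <- 1 / lip
  for (k in seq_len(n_steps)) {
    g <- W
    for (m in seq_len(M)) {
      rn <- sqrt(rowSums(W[[m]]^2))
      dir <- W[[m]] / ifelse(rn > 0, rn, 1)
      dir[rn == 0, ] <- 0
      for (t in seq_len(T_)) {
        g[[m]][, t] <- drop(G[[m]][[t]] %*% W[[m]][, t]) - b[[m]][[t]]
      }
      g[[m]] <- g[[m]] + beta * dir
      if (T_ > 1) {
        sg <- sign(W[[m]][, -1, drop = FALSE] - W[[m]][, -T_, drop = FALSE])
        g[[m]][, -1] <- g[[m]][, -1] + mu * sg
        g[[m]][, -T_] <- g[[m]][, -T_] - mu * sg
      }
    }
    W <- Map(function(Wm, gm) Wm - (step0 / sqrt(k)) * gm, W, g)
    best <- min(best, obj(W))
  }
  best
}

# vectorized twin of objective_loops, for use inside the subgradient loop
objective_loops_fast <- function(data, laps, W, beta, lambda, mu) {
  Y <- data$labels
  total <- 0
  for (m in seq_along(data$features)) {
    Wm <- W[[m]]
    for (t in seq_along(data$features[[m]])) {
      s <- drop(data$features[[m]][[t]] %*% Wm[, t])
      total <- total + 0.5 * sum((Y - s)^2)
      if (lambda > 0) {
        total <- total + lambda * drop(crossprod(s, laps[[m]][[t]]$matrix %*% s))
      }
    }
    total <- total + beta * sum(sqrt(rowSums(Wm^2)))
    if (ncol(Wm) > 1) {
      total <- total + mu *
        sum(abs(Wm[, -1, drop = FALSE] - Wm[, -ncol(Wm), drop = FALSE]))
    }
  }
  total
}

# --- KNN membership by exhaustive distance sort ---------------------------
knn_oracle <- function(features, k) {
  n <- nrow(features)
  lapply(seq_len(n), function(i) {
    dd <- sqrt(colSums((t(features) - features[i, ])^2))
    cand <- setdiff(seq_len(n), i)
    nn <- cand[order(dd[cand], cand)][seq_len(k)]
    sort(c(i, nn))
  })
}

# --- confusion-matrix metrics by explicit loops ---------------------------
metrics_oracle <- function(truth, pred, scores = NULL) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(truth)) {
    if (truth[i] == 1 && pred[i] == 1) tp <- tp + 1
    if (truth[i] == -1 && pred[i] == 1) fp <- fp + 1
    if (truth[i] == -1 && pred[i] == -1) tn <- tn + 1
    if (truth[i] == 1 && pred[i] == -1) fn <- fn + 1
  }
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA
  rec <- tp / (tp + fn)
  out <- list(
    accuracy = (tp + tn) / length(truth),
    sensitivity = rec,
    specificity = tn / (tn + fp),
    f1 = if (!is.na(prec) && prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  )
  if (!is.null(scores)) {
    # Mann-Whitney with half credit for ties: equals the trapezoidal area
    pos <- scores[truth == 1]
    neg <- scores[truth == -1]
    wins <- 0
    for (a in pos) for (b in neg) {
      wins <- wins + (a > b) + 0.5 * (a == b)
    }
    out$auc <- wins / (length(pos) * length(neg))
  }
  out
}

# --- misc -----------------------------------------------------------------
support_f1 <- function(selected, planted) {
  tp <- length(intersect(selected, planted))
  p <- if (length(selected)) tp / length(selected) else 0
  r <- tp / length(planted)
  if (p + r > 0) 2 * p * r / (p + r) else 0
}

random_hypergraph <- function(n, ne, weights = FALSE) {
  repeat {
    H <- matrix(rbinom(n * ne, 1, 0.4), n, ne)
    if (all(colSums(H) > 0) && all(rowSums(H) > 0)) break
  }
  w <- if (weights) runif(ne, 0.2, 3) else NULL
  hypergraph(H, w)
}
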