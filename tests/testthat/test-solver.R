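test_that("objective matches the scalar-loop expansion", {
  co <- tiny_cohort(n = 4, d = 3, T_ = 2, M = 1, seed = 3)
  laps <- fixture_laps(co, k = 2)
  params <- hf_params(beta = 0.7, lambda = 0.3, mu = 0.5)
  set.seed(9)
  W <- random_weights(co)
  expect_equal(hf_objective(co, laps, W, params),
               objective_loops(co, laps, W, 0.7, 0.3, 0.5),
               tolerance = 1e-10)

  # W = 0: all penalties vanish, leaving 0.5 * M * T * ||Y||^2
  co2 <- tiny_cohort(n = 8, d = 3, T_ = 3, M = 2, seed = 4)
  W0 <- lapply(1:2, function(m) matrix(0, 3, 3))
  expect_equal(hf_objective(co2, NULL, W0, hf_params(lambda = 0)),
               0.5 * 2 * 3 * sum(co2$labels^2))

  # identical columns per modality: the fused term contributes exactly zero
  set.seed(10)
  w_col <- rnorm(3)
  W_const <- lapply(1:2, function(m) matrix(w_col, 3, 3))
  p0 <- hf_params(beta = 0, lambda = 0, mu = 0)
  p_mu <- hf_params(beta = 0, lambda = 0, mu = 4.2)
  expect_equal(hf_objective(co2, NULL, W_const, p_mu),
               hf_objective(co2, NULL, W_const, p0))
})

test_that("objective validates shapes and hyperparameters", {
  co <- tiny_cohort(n = 4, d = 3, T_ = 2, M = 1)
  W_bad <- list(matrix(0, 2, 2))
  expect_error(hf_objective(co, NULL, W_bad, hf_params(lambda = 0)),
               "dimension mismatch")
  expect_error(hf_params(beta = -1), ">= 0")
})

test_that("smooth gradient matches finite differences and closed forms", {
  co <- tiny_cohort(n = 6, d = 3, T_ = 2, M = 1, seed = 12)
  laps <- fixture_laps(co, k = 2)
  params <- hf_params(beta = 0, lambda = 0.4, mu = 0)
  set.seed(13)
  W <- random_weights(co, sd = 0.5)
  g <- hf_gradient(co, laps, W, params)
  h <- function(W) {
    # smooth part only (beta = mu = 0 makes the objective purely smooth)
    hf_objective(co, laps, W, params)
  }
  eps <- 1e-6
  for (j in 1:3) {
    for (t in 1:2) {
      Wp <- W; Wm <- W
      Wp[[1]][j, t] <- Wp[[1]][j, t] + eps
      Wm[[1]][j, t] <- Wm[[1]][j, t] - eps
      expect_equal(g[[1]][j, t], (h(Wp) - h(Wm)) / (2 * eps),
                   tolerance = 1e-5)
    }
  }

  # orthonormal columns, lambda = 0: gradient reduces to w - X'Y
  Q <- qr.Q(qr(matrix(rnorm(18), 6, 3)))
  co_o <- cohort(list(list(Q)), labels = rep(c(-1, 1), 3))
  p0 <- hf_params(lambda = 0)
  W1 <- list(matrix(rnorm(3), 3, 1))
  g1 <- hf_gradient(co_o, NULL, W1, p0)
  expect_equal(g1[[1]], W1[[1]] - crossprod(Q, co_o$labels), tolerance = 1e-10)

  # at the least-squares minimizer with lambda = 0 the gradient vanishes
  X <- co$features[[1]][[1]]
  w_ls <- solve(crossprod(X), crossprod(X, co$labels))
  W_ls <- list(cbind(w_ls, solve(crossprod(co$features[[1]][[2]]),
                                 crossprod(co$features[[1]][[2]], co$labels))))
  g_ls <- hf_gradient(co, NULL, W_ls, p0)
  expect_lt(max(abs(g_ls[[1]])), 1e-8)
})

test_that("with all penalties off the solver recovers least squares", {
  co <- tiny_cohort(n = 20, d = 5, T_ = 1, M = 1, seed = 21)
  fit <- hf_fit(co, hf_params(beta = 0, lambda = 0, mu = 0, tol = 1e-12,
                              max_iter = 5000),
                standardize = FALSE)
  X <- co$features[[1]][[1]]
  w_pinv <- MASS::ginv(X) %*% co$labels
  expect_lt(max(abs(fit$W[[1]] - w_pinv)), 1e-6)
})

test_that("a huge group penalty forces the zero solution", {
  co <- tiny_cohort(n = 10, d = 4, T_ = 2, M = 2, seed = 22)
  fit <- hf_fit(co, hf_params(beta = 1e6, lambda = 0, mu = 0.1))
  expect_true(all(vapply(fit$W, function(Wm) all(Wm == 0), logical(1))))
  expect_equal(nrow(hf_select(fit)$by_cell), 0L)
})

test_that("APG reaches at least subgradient-descent quality; trace monotone", {
  co <- tiny_cohort(n = 20, d = 10, T_ = 2, M = 1, seed = 31)
  laps <- fixture_laps(co, k = 3)
  configs <- list(
    no_hypergraph = c(beta = 2, lambda = 0, mu = 1),   # fused sparse group
    l21_only = c(beta = 2, lambda = 0, mu = 0)         # plain multi-task
  )
  for (nm in names(configs)) {
    cf <- configs[[nm]]
    params <- hf_params(beta = cf["beta"], lambda = cf["lambda"],
                        mu = cf["mu"], tol = 1e-10, max_iter = 3000)
    fit <- hf_fit(co, params, standardize = FALSE,
                  laplacians = if (cf["lambda"] > 0) laps else NULL)
    trace <- fit$objective_trace
    expect_true(all(diff(trace) <= 1e-10 * pmax(1, abs(trace[-length(trace)]))),
                info = nm)
    best_sub <- subgrad_oracle(co, laps, cf["beta"], cf["lambda"], cf["mu"],
                               n_steps = 12000)
    expect_lte(trace[length(trace)], best_sub + 1e-4)
  }
})

test_that("momentum restarts keep the trace monotone on a hard instance", {
  co <- tiny_cohort(n = 12, d = 8, T_ = 3, M = 2, seed = 41)
  params <- hf_params(beta = 1, lambda = 0.5, mu = 2, tol = 1e-9,
                      max_iter = 2000, k = 3)
  fit <- hf_fit(co, params)
  trace <- fit$objective_trace
  expect_true(all(diff(trace) <= 1e-10 * pmax(1, abs(trace[-length(trace)]))))
})

test_that("a large fused penalty flattens the temporal profiles", {
  co <- simulate_cohort(sim_spec(n_per_class = 25, d = 12, n_timepoints = 3,
                                 n_modalities = 1, n_informative = 4,
                                 effect_base = 1, effect_slope = 0.6),
                        seed = 51)
  tv_total <- function(fit) {
    sum(vapply(fit$W, function(Wm) {
      sum(abs(Wm[, -1, drop = FALSE] - Wm[, -ncol(Wm), drop = FALSE]))
    }, numeric(1)))
  }
  fit_rough <- hf_fit(co, hf_params(beta = 1, lambda = 0, mu = 1e-4,
                                    max_iter = 2000, tol = 1e-9))
  fit_smooth <- hf_fit(co, hf_params(beta = 1, lambda = 0, mu = 5,
                                     max_iter = 2000, tol = 1e-9))
  expect_lte(tv_total(fit_smooth), tv_total(fit_rough))
})

test_that("feature selection reports thresholded cells and unions", {
  W <- list(mod1 = rbind(c(0, 0, 0), c(0.5, 0.4, 0), c(0, 0, 0)),
            mod2 = matrix(0, 3, 3))
  sel <- hf_select(W, threshold = 1e-8)
  expect_equal(sel$by_modality$mod1, 2L)
  expect_equal(sel$by_modality$mod2, integer())
  expect_equal(sort(sel$by_cell$timepoint), c(1L, 2L))
  sel0 <- hf_select(list(matrix(0, 2, 2)))
  expect_equal(nrow(sel0$by_cell), 0L)
  expect_equal(lengths(sel0$by_modality), c(mod1 = 0L))
})

test_that("solver flags non-convergence with a warning, not an error", {
  co <- tiny_cohort(n = 10, d = 6, T_ = 2, M = 1, seed = 61)
  expect_warning(
    fit <- hf_fit(co, hf_params(beta = 0.5, lambda = 0, mu = 0.5,
                                max_iter = 2, tol = 1e-14)),
    "did not converge"
  )
  expect_false(fit$converged)
})
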