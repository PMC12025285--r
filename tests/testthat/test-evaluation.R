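test_that("metrics match the hand-worked confusion matrix", {
  # TP=3, FP=1, TN=4, FN=2
  truth <- c(rep(1, 5), rep(-1, 5))
  pred <- c(1, 1, 1, -1, -1, 1, -1, -1, -1, -1)
  m <- compute_metrics(truth, pred)
  expect_equal(m$sensitivity, 0.6)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$precision, 0.75)
  expect_equal(m$f1, 2 * 0.75 * 0.6 / (0.75 + 0.6))
  expect_equal(round(m$f1, 3), 0.667)
})

test_that("metrics agree with an independent loop oracle on random vectors", {
  set.seed(71)
  for (rep in 1:100) {
    n <- sample(6:40, 1)
    truth <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(truth)) < 2) truth[1:2] <- c(-1, 1)
    pred <- sample(c(-1, 1), n, replace = TRUE)
    scores <- round(rnorm(n), 1)  # rounding forces score ties
    m <- compute_metrics(truth, pred, scores)
    o <- metrics_oracle(truth, pred, scores)
    expect_equal(m$accuracy, o$accuracy)
    expect_equal(m$sensitivity, o$sensitivity)
    expect_equal(m$specificity, o$specificity)
    expect_equal(m$f1, o$f1)
    expect_equal(m$auc, o$auc, tolerance = 1e-12)
  }
})

test_that("metrics agree with pROC on random score vectors", {
  skip_if_not_installed("pROC")
  set.seed(72)
  for (rep in 1:20) {
    n <- 30
    truth <- c(rep(1, 15), rep(-1, 15))
    scores <- rnorm(n) + truth
    m <- compute_metrics(truth, sign(scores), scores)
    ref <- suppressMessages(pROC::auc(pROC::roc(truth, scores)))
    expect_equal(m$auc, as.numeric(ref), tolerance = 1e-10)
  }
})

test_that("perfect and reversed predictions hit the metric boundaries", {
  truth <- c(rep(1, 4), rep(-1, 4))
  scores <- c(4, 3, 2.5, 2, 1, 0.5, 0, -1)
  m <- compute_metrics(truth, truth, scores)
  expect_equal(m$accuracy, 1)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$f1, 1)
  expect_equal(m$auc, 1)
  m_rev <- compute_metrics(truth, truth, -scores)
  expect_equal(m_rev$auc, 0)
  expect_error(compute_metrics(rep(1, 4), rep(1, 4)), "both classes")
  expect_error(compute_metrics(truth, truth[-1]), "lengths differ")
})

test_that("cross-validation is perfect on a separable cohort", {
  co <- separable_cohort(n_per_class = 15, d = 4, T_ = 2, M = 1, sep = 8,
                         seed = 81)
  cv <- hf_cv(co, hf_params(beta = 3, lambda = 0, mu = 0.5, max_iter = 300,
                            tol = 1e-5),
              folds = 5, seed = 4)
  expect_equal(cv$pooled$accuracy, 1)
  expect_equal(cv$pooled$sensitivity, 1)
  expect_equal(cv$pooled$specificity, 1)
  expect_equal(cv$pooled$f1, 1)
  expect_equal(cv$pooled$auc, 1)
})

test_that("null cohorts classify at chance level", {
  preds <- list()
  for (s in 1:10) {
    co <- simulate_cohort(sim_spec(n_per_class = 20, d = 15, n_timepoints = 2,
                                   n_modalities = 2, n_informative = 0,
                                   effect_base = 0), seed = 8000 + s)
    cv <- hf_cv(co, hf_params(beta = 2, lambda = 0, mu = 0.5, max_iter = 150,
                              tol = 1e-4),
                folds = 5, seed = s, weight_grid_step = 0.5)
    preds[[s]] <- cv$predictions
  }
  all_preds <- do.call(rbind, preds)
  acc <- mean(all_preds$pred == all_preds$truth)
  n <- nrow(all_preds)  # 400 pooled predictions
  expect_lt(abs(acc - 0.5), 1.96 * sqrt(0.25 / n) + 0.02)
})

test_that("folds are stratified, seeded and reproducible", {
  co <- simulate_cohort(sim_spec(n_per_class = 20, d = 6, n_timepoints = 2,
                                 n_modalities = 1, n_informative = 2),
                        seed = 9)
  params <- hf_params(beta = 3, lambda = 0, mu = 0.5, max_iter = 200,
                      tol = 1e-4)
  cv1 <- hf_cv(co, params, folds = 5, seed = 11)
  cv2 <- hf_cv(co, params, folds = 5, seed = 11)
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(cv1$predictions, cv2$predictions)
  expect_identical(cv1$pooled, cv2$pooled)
  # each fold is class-balanced for balanced input
  tab <- table(cv1$folds, co$labels)
  expect_true(all(tab == 4))
  expect_error(hf_cv(co, params, folds = 25), "too few subjects")
})

test_that("test-fold labels never influence fitting or selection", {
  co <- simulate_cohort(sim_spec(n_per_class = 15, d = 8, n_timepoints = 2,
                                 n_modalities = 1, n_informative = 3),
                        seed = 14)
  params <- hf_params(beta = 4, lambda = 0.01, mu = 0.5, k = 3,
                      max_iter = 200, tol = 1e-4)
  cv <- hf_cv(co, params, folds = 5, seed = 2)
  # permute the labels of fold 1's test subjects and rerun
  test_idx <- which(cv$folds == 1)
  co_perm <- co
  co_perm$labels[test_idx] <- rev(co_perm$labels[test_idx])
  res <- hyperfuse:::run_fold(co, params, test_idx, weight_grid_step = 0.1,
                              C = 1, inner_folds = 10, inner_seed = 77)
  res_perm <- hyperfuse:::run_fold(co_perm, params, test_idx,
                                   weight_grid_step = 0.1, C = 1,
                                   inner_folds = 10, inner_seed = 77)
  expect_identical(res$selection$by_cell, res_perm$selection$by_cell)
  expect_identical(res$mix_weights, res_perm$mix_weights)
  expect_identical(res$predictions$pred, res_perm$predictions$pred)
  expect_identical(res$predictions$score, res_perm$predictions$score)
})

test_that("stability counts are bounded by folds and deterministically ranked", {
  co <- simulate_cohort(sim_spec(n_per_class = 20, d = 10, n_timepoints = 2,
                                 n_modalities = 2, n_informative = 3,
                                 effect_base = 2), seed = 16)
  cv <- hf_cv(co, hf_params(beta = 8, lambda = 0, mu = 1, max_iter = 200,
                            tol = 1e-4),
              folds = 5, seed = 3, weight_grid_step = 0.5, top_k = 5)
  st <- cv$stability
  expect_true(all(st$count <= 5))
  expect_true(all(st$count >= 1))
  for (mod in unique(st$modality)) {
    sub <- st[st$modality == mod, ]
    expect_true(all(diff(sub$count) <= 0))
    ties <- split(sub$feature, sub$count)
    expect_true(all(vapply(ties, function(x) all(diff(x) >= 0) || length(x) == 1,
                           logical(1))))
    expect_lte(nrow(sub), 5)
  }
  # planted features dominate the ranking
  top1 <- st$feature[st$modality == "mod1" & st$rank <= 3]
  expect_gte(length(intersect(top1, ground_truth(co)$mod1)), 2)
})

test_that("ablation covers the four canonical configurations", {
  co <- simulate_cohort(sim_spec(n_per_class = 15, d = 8, n_timepoints = 2,
                                 n_modalities = 1, n_informative = 3),
                        seed = 18)
  params <- hf_params(beta = 4, lambda = 0.01, mu = 0.5, k = 3,
                      max_iter = 150, tol = 1e-4)
  tab <- hf_ablation_table(co, params, folds = 5, seed = 6)
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$configuration,
               c("none", "group_sparsity", "group_and_hypergraph", "full"))
  # which = {} must equal a plain cross-validation
  cv_plain <- hf_cv(co, params, folds = 5, seed = 6)
  cv_noop <- hf_ablation(co, params, which = character(), folds = 5, seed = 6)
  expect_identical(cv_plain$pooled, cv_noop$pooled)
  expect_error(hf_ablation(co, params, which = "gamma"), "unknown")
})

test_that("sweep enumerates the grid and a singleton grid equals plain CV", {
  expect_equal(length(default_reg_grid()), 10L)
  expect_equal(length(default_k_grid()), 8L)
  expect_equal(default_reg_grid()[1], 1e-4)
  expect_equal(default_k_grid(), c(3, 5, 7, 10, 15, 20, 25, 30))

  co <- simulate_cohort(sim_spec(n_per_class = 15, d = 8, n_timepoints = 2,
                                 n_modalities = 1, n_informative = 3),
                        seed = 19)
  params <- hf_params(beta = 4, lambda = 0, mu = 0.5, max_iter = 150,
                      tol = 1e-4)
  tab <- hf_sweep(co, params, grid = list(beta = c(2, 4), mu = c(0.1, 1)),
                  folds = 5, seed = 7)
  expect_equal(nrow(tab), 4L)
  expect_setequal(tab$beta, c(2, 4))
  single <- hf_sweep(co, params, grid = list(beta = 4), folds = 5, seed = 7)
  expect_equal(nrow(single), 1L)
  cv <- hf_cv(co, params, folds = 5, seed = 7)
  expect_equal(single$accuracy, cv$pooled$accuracy)
  expect_equal(single$auc, cv$pooled$auc)
})
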