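# hyperfuse

Sparse multi-task feature selection and classification for **longitudinal
multimodal cohorts** — the setting of serial neuroimaging studies where
each subject is measured on the same d regional features at T visits in M
modalities, with one binary diagnosis per subject. Typical users are
researchers building imaging-based classifiers (e.g. case vs. control
from fMRI + sMRI region-of-interest summaries) who want the selected
features to be sparse, stable across visits, and interpretable.

## The model

Feature selection at each (modality m, visit t) is one task with
coefficients `w_mt`; the tasks are fitted jointly by minimizing

```
  1/2 Σ_mt ||y − X_mt w_mt||²                 (squared loss, shared labels y ∈ {−1,+1})
+ β  Σ rows ||w_row||₂                        (ℓ2,1: keep/drop a feature jointly across visits)
+ λ  Σ_mt (X_mt w_mt)' L_mt (X_mt w_mt)       (KNN-hypergraph Laplacian: respect subject similarity)
+ μ  Σ_m Σ_t ||w_m,t+1 − w_mt||₁              (fused lasso: temporally smooth coefficient profiles)
```

where `L_mt = I − Dv^{−1/2} H W De^{−1} H' Dv^{−1/2}` is the normalized
Laplacian of a k-nearest-neighbour hypergraph built over the training
subjects of that cell. The objective is minimized by a monotone
accelerated proximal gradient method with backtracking; the non-smooth
part has an exact two-stage proximal operator (1-D fused-lasso signal
approximation per coefficient row, then group soft-thresholding), with
the fused-lasso prox solved by a direct taut-string sweep in C++.
Selected features are concatenated across visits per modality, turned
into linear Gram matrices, fused as a convex combination
`K = Σ_m β_m K_m` with simplex weights grid-searched by inner ten-fold
cross-validation, and classified by an SVM (C = 1) on the precomputed
mixed kernel.

The package also ships a synthetic longitudinal cohort generator with
planted, progressively growing effects (so every stage is testable
without any data download), stratified outer cross-validation with
ROC/AUC and feature-stability reporting, ablation and hyperparameter
sweep runners, CSV/YAML readers and writers, and a command-line
interface (`inst/cli/hyperfuse.R` with subcommands
`simulate | fit | evaluate | ablate | sweep`).

## A worked example

```r
library(hyperfuse)

co  <- simulate_cohort(sim_spec(n_per_class = 50), seed = 1)
fit <- hf_fit(co, hf_params(beta = 25, lambda = 0.5, mu = 5, k = 7))
glance(fit)
#> # A tibble: 1 × 8
#>   iterations converged objective n_selected  beta lambda    mu     k
#>        <int> <lgl>         <dbl>      <int> <dbl>  <dbl> <dbl> <int>
#> 1         12 TRUE           267.         27    25    0.5     5     7

ground_truth(co)$mod1          # planted informative features, modality 1
#>  [1]  1 14 21 34 39 43 51 59 68 82
hf_select(fit)$by_modality$mod1
#>  [1]  1  2 12 14 21 34 37 39 43 50 51 59 68 82

cv <- hf_cv(co, hf_params(beta = 25, lambda = 0.5, mu = 5, k = 7,
                          max_iter = 200, tol = 1e-4),
            folds = 10, seed = 1)
cv
#> <hf_cv> 10 folds, 100 subjects
#>   pooled: ACC 100.00%  SEN 100.00%  SPE 100.00%  F1 100.00%  AUC 1.0000
```

The fit converges in a dozen accelerated iterations, recovers all ten
planted features of the modality (plus four false positives at this
moderate `beta`), and the cross-validated classifier separates the
two classes perfectly — expected here, because the planted effects
(1.5 SD at baseline, growing by 0.25 SD per visit, ten features per
modality) are strong at this sample size. `autoplot(cv, "roc")`,
`autoplot(cv, "stability")` and `autoplot(fit, "weights")` draw the
standard diagnostics; `tidy()`/`glance()` methods return tibbles for all
result types.

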