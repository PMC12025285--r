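# Fixture builders; everything is generated in code under fixed seeds.

# A small random cohort with no structure (pure noise unless effects given).
tiny_cohort <- function(n = 10, d = 4, T_ = 2, M = 1, seed = 1,
                        effect = 0, n_informative = 0) {
  simulate_cohort(
    sim_spec(n_per_class = n / 2, d = d, n_timepoints = T_, n_modalities = M,
             n_informative = n_informative, effect_base = effect,
             effect_slope = 0, subject_sd = 0),
    seed = seed
  )
}

# Two well-separated Gaussian blobs in every feature of modality 1; pure
# noise in modality 2 (when M = 2).
separable_cohort <- function(n_per_class = 15, d = 5, T_ = 2, M = 2,
                             sep = 8, seed = 1) {
  co <- simulate_cohort(
    sim_spec(n_per_class = n_per_class, d = d, n_timepoints = T_,
             n_modalities = 1, n_informative = d, effect_base = sep,
             effect_slope = 0, noise_sd = 1, subject_sd = 0),
    seed = seed
  )
  if (M == 1) return(co)
  set.seed(seed + 9000)
  noise <- lapply(seq_len(M - 1), function(m) {
    lapply(seq_len(T_), function(t) {
      matrix(rnorm(2 * n_per_class * d), 2 * n_per_class, d)
    })
  })
  out <- cohort(c(co$features, noise), co$labels,
                modality_names = paste0("mod", seq_len(M)))
  attr(out, "ground_truth") <- c(
    ground_truth(co),
    stats::setNames(replicate(M - 1, integer(), simplify = FALSE),
                    paste0("mod", 2:M))
  )
  out
}

# Random weight tensor shaped like `data`.
random_weights <- function(data, sd = 1) {
  lapply(seq_len(n_modalities(data)), function(m) {
    matrix(rnorm(n_features(data) * n_timepoints(data), sd = sd),
           n_features(data), n_timepoints(data))
  })
}

# Laplacians for all cells (unscaled distances, raw features).
fixture_laps <- function(data, k = 2) cohort_laplacians(data, k, scale = FALSE)
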