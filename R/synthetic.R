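#' Specification of a synthetic longitudinal multimodal cohort
#'
#' The generator emulates a two-class longitudinal design of
#' region-of-interest summaries: M modalities observed at T visits over the
#' same d features, with a sparse set of informative features whose class
#' separation grows linearly across visits (progressive change). The
#' defaults mirror a 90-region, 4-visit, 2-modality design.
#'
#' A feature value is
#' `x[i, j, t, m] = a_i + 1(y_i = +1) * Delta(j, t, m) + e`,
#' where `a_i ~ N(0, subject_sd)` is a shared subject random effect (the
#' source of within-subject temporal correlation),
#' `Delta = effect_base + (t - 1) * effect_slope` for features planted in
#' modality m (0 otherwise), and `e ~ N(0, noise_sd)` is independent
#' feature-wise noise.
#'
#' @param n_per_class subjects per class (labels are balanced).
#' @param d number of features per cell.
#' @param n_timepoints number of visits T.
#' @param n_modalities number of modalities M.
#' @param n_informative number of planted informative features per modality.
#' @param effect_base mean class separation, in noise-SD units, at the
#'   first visit.
#' @param effect_slope per-visit increment of the class separation.
#' @param cross_modality_overlap fraction of informative features shared
#'   between modalities (in \[0, 1\]).
#' @param noise_sd standard deviation of the feature-wise noise.
#' @param subject_sd standard deviation of the additive subject random
#'   effect.
#' @return an object of class `sim_spec`.
#' @export
sim_spec <- function(n_per_class = 200, d = 90, n_timepoints = 4,
                     n_modalities = 2, n_informative = 10,
                     effect_base = 1.5, effect_slope = 0.25,
                     cross_modality_overlap = 0.5, noise_sd = 1,
                     subject_sd = 0.5) {
  if (n_per_class < 2) abort("degenerate spec: need at least 2 subjects per class")
  if (n_informative > d) abort("degenerate spec: n_informative exceeds d")
  if (n_informative < 0 || d < 1 || n_timepoints < 1 || n_modalities < 1) {
    abort("degenerate spec: counts must be positive")
  }
  if (noise_sd < 0 || subject_sd < 0) abort("degenerate spec: SDs must be >= 0")
  if (cross_modality_overlap < 0 || cross_modality_overlap > 1) {
    abort("degenerate spec: cross_modality_overlap must lie in [0, 1]")
  }
  structure(
    list(n_per_class = as.integer(n_per_class), d = as.integer(d),
         n_timepoints = as.integer(n_timepoints),
         n_modalities = as.integer(n_modalities),
         n_informative = as.integer(n_informative),
         effect_base = effect_base, effect_slope = effect_slope,
         cross_modality_overlap = cross_modality_overlap,
         noise_sd = noise_sd, subject_sd = subject_sd),
    class = "sim_spec"
  )
}

#' @export
print.sim_spec <- function(x, ...) {
  cat(sprintf(
    "<sim_spec> %d/class x %d features, %d modalities x %d visits; %d informative (base %g, slope %g)\n",
    x$n_per_class, x$d, x$n_modalities, x$n_timepoints, x$n_informative,
    x$effect_base, x$effect_slope))
  invisible(x)
}

#' Generate a synthetic longitudinal multimodal cohort
#'
#' See [sim_spec()] for the generative model. The output is fully
#' determined by `seed`: the same seed yields a bitwise-identical cohort.
#'
#' @param spec a [sim_spec()].
#' @param seed integer seed driving all randomness.
#' @return a [cohort()] carrying the planted informative feature indices
#'   per modality as the `ground_truth` attribute (see [ground_truth()]).
#' @examples
#' co <- simulate_cohort(sim_spec(n_per_class = 10, d = 15), seed = 7)
#' ground_truth(co)
#' @export
simulate_cohort <- function(spec = sim_spec(), seed = 1) {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(seed, {
    n <- 2L * spec$n_per_class
    labels <- rep(c(1, -1), each = spec$n_per_class)
    case <- as.numeric(labels == 1)

    planted <- vector("list", spec$n_modalities)
    planted[[1]] <- sort(sample.int(spec$d, spec$n_informative))
    if (spec$n_modalities > 1L) {
      n_shared <- round(spec$cross_modality_overlap * spec$n_informative)
      for (m in 2:spec$n_modalities) {
        shared <- if (n_shared > 0) sort(sample(planted[[1]], n_shared)) else integer()
        pool <- setdiff(seq_len(spec$d), planted[[1]])
        fresh <- if (spec$n_informative - n_shared > 0) {
          sort(sample(pool, spec$n_informative - n_shared))
        } else integer()
        planted[[m]] <- sort(c(shared, fresh))
      }
    }

    subj_eff <- rnorm(n, 0, spec$subject_sd)
    feats <- lapply(seq_len(spec$n_modalities), function(m) {
      lapply(seq_len(spec$n_timepoints), function(t) {
        delta <- numeric(spec$d)
        delta[planted[[m]]] <- spec$effect_base + (t - 1) * spec$effect_slope
        noise <- matrix(rnorm(n * spec$d, 0, spec$noise_sd), n, spec$d)
        subj_eff + outer(case, delta) + noise
      })
    })
    out <- cohort(feats, labels)
    attr(out, "ground_truth") <- stats::setNames(planted, out$modality_names)
    out
  })
}

#' Degrade a cohort with label noise and extra feature noise
#'
#' A reproducible stress harness: flips exactly
#' `floor(flip_fraction * N)` labels (chosen uniformly at random under
#' `seed`) and adds independent Gaussian noise of SD `extra_noise_sd` to
#' every feature value.
#'
#' @param data a [cohort()].
#' @param flip_fraction fraction of labels to flip, in \[0, 0.5).
#' @param extra_noise_sd SD of the added feature noise (>= 0).
#' @param seed integer seed.
#' @return a degraded [cohort()]; the `ground_truth` attribute, if any, is
#'   preserved.
#' @export
degrade_cohort <- function(data, flip_fraction = 0, extra_noise_sd = 0,
                           seed = 1) {
  stopifnot(inherits(data, "cohort"))
  if (flip_fraction < 0 || flip_fraction >= 0.5) {
    abort("`flip_fraction` must lie in [0, 0.5)")
  }
  if (extra_noise_sd < 0) abort("`extra_noise_sd` must be >= 0")
  with_seed(seed, {
    n <- n_subjects(data)
    out <- data
    n_flip <- floor(flip_fraction * n)
    if (n_flip > 0) {
      idx <- sample.int(n, n_flip)
      out$labels[idx] <- -out$labels[idx]
    }
    if (extra_noise_sd > 0) {
      out$features <- lapply(out$features, function(cells) {
        lapply(cells, function(mat) {
          mat + matrix(rnorm(length(mat), 0, extra_noise_sd),
                       nrow(mat), ncol(mat))
        })
      })
    }
    out
  })
}
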