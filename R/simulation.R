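#' Null rejection-rate simulation for the pooled t-test
#'
#' Both groups are generated from the SAME sample spec, so the pooled
#' two-sample t-test on the resulting sample mean ratios should reject at
#' its nominal level. Each simulated sample's mean ratio is the mean of
#' `k_cells` per-cell true-ratio draws from the spec's distribution (the
#' generator's truth layer; no rasterization, which the measurement tests
#' cover separately).
#'
#' @param n_per_group samples per group in each replicate
#' @param true_spec a [sample_spec()] supplying `true_mean_ratio` and
#'   `between_cell_sd`
#' @param reps number of replicates (>= 100)
#' @param alpha nominal level; a replicate counts as a rejection when
#'   `p < alpha`
#' @param seed integer seed
#' @param k_cells cells per simulated sample collection (default 30)
#' @param between_sample_sd optional SD of per-sample true means (default 0:
#'   all samples share the spec's mean)
#' @return the rejection rate (fraction of replicates with `p < alpha`)
#' @export
type_one_error_sim <- function(n_per_group, true_spec, reps, alpha, seed,
                               k_cells = 30L, between_sample_sd = 0) {
  stopifnot(reps >= 100L, n_per_group >= 2L, alpha >= 0, alpha <= 1)
  rejection_rate_truth(
    mean_a = true_spec$true_mean_ratio, mean_b = true_spec$true_mean_ratio,
    cell_sd = true_spec$between_cell_sd,
    sample_sd_a = between_sample_sd, sample_sd_b = between_sample_sd,
    n_a = n_per_group, n_b = n_per_group, k_cells = k_cells,
    reps = reps, alpha = alpha, seed = seed)
}

#' Rejection rate of the pooled t-test on the generator's truth layer
#'
#' Each replicate draws `n_a` and `n_b` sample mean ratios: a sample's
#' true mean comes from Normal(group mean, sample SD) truncated at zero,
#' and its observed mean ratio is the average of `k_cells` cell-level
#' draws around that mean. The pooled two-sided t-test is applied and
#' rejections at `alpha` are counted.
#'
#' @param mean_a,mean_b group-level true mean ratios
#' @param cell_sd between-cell SD within a sample
#' @param sample_sd_a,sample_sd_b between-sample SDs of the true means
#' @param n_a,n_b samples per group
#' @param k_cells cells per sample collection
#' @param reps replicates
#' @param alpha level (rejection when `p < alpha`)
#' @param seed integer seed
#' @return fraction of replicates rejected
#' @export
rejection_rate_truth <- function(mean_a, mean_b, cell_sd,
                                 sample_sd_a = 0, sample_sd_b = 0,
                                 n_a = 9L, n_b = 30L, k_cells = 30L,
                                 reps = 1000L, alpha = 0.05, seed = 1L) {
  stopifnot(n_a >= 2L, n_b >= 2L, reps >= 1L)
  draw_group <- function(n, mu, ssd) {
    mus <- rnorm_trunc0(n, mu, ssd)
    vapply(mus, function(m) mean(rnorm_trunc0(k_cells, m, cell_sd)), numeric(1))
  }
  withr::with_seed(as.integer(seed %% 2147483647), {
    rej <- logical(reps)
    for (r in seq_len(reps)) {
      a <- draw_group(n_a, mean_a, sample_sd_a)
      b <- draw_group(n_b, mean_b, sample_sd_b)
      rej[r] <- t_test_groups(a, b, "t_pooled")$p_value < alpha
    }
    mean(rej)
  })
}

#' Rejection rate of the pooled t-test over full pipeline replicates
#'
#' Each replicate builds two groups of samples (per-sample true means drawn
#' around the group means), renders every field in memory, measures the
#' cells, draws the fixed-size collections, and applies the pooled t-test
#' to the resulting sample mean ratios. This is the end-to-end power (or
#' size) of the study design including measurement noise.
#'
#' @param group_a,group_b lists with elements `label`, `n_samples`,
#'   `mean_ratio`, `between_sample_sd`
#' @param reps number of replicates
#' @param alpha level (rejection when `p < alpha`)
#' @param seed integer seed
#' @param k_cells collection size per sample
#' @param ... template arguments passed to [sample_spec()] via
#'   [group_sample_specs()] (e.g. `n_images`, `cells_per_image`,
#'   `pixel_noise_sd`)
#' @return fraction of replicates rejected
#' @export
rejection_rate_pipeline <- function(group_a, group_b, reps = 100L,
                                    alpha = 0.05, seed = 1L, k_cells = 30L,
                                    ...) {
  sim_group <- function(g, rep_seed) {
    specs <- group_sample_specs(g$label, g$n_samples, g$mean_ratio,
                                g$between_sample_sd,
                                seed = rep_seed, ...)
    vapply(specs, function(sp) simulate_sample_summary(sp, k_cells)$mean_ratio,
           numeric(1))
  }
  rej <- logical(reps)
  for (r in seq_len(reps)) {
    a <- sim_group(group_a, derive_seed(seed, "rep", r, group_a$label))
    b <- sim_group(group_b, derive_seed(seed, "rep", r, group_b$label))
    rej[r] <- t_test_groups(a, b, "t_pooled")$p_value < alpha
  }
  mean(rej)
}
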