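# Shared fixtures: everything is generated in code at test time.

# A small, fast sample spec for pipeline-level tests.
tiny_spec <- function(sample_id = "S1", group = "g", mean_ratio = 0.6,
                      seed = 1L, ...) {
  args <- list(sample_id = sample_id, group_label = group,
               true_mean_ratio = mean_ratio, seed = seed,
               n_images = 2L, cells_per_image = 8L,
               image_shape = c(64L, 64L), pixel_noise_sd = 0,
               between_cell_sd = 0.05, red_cell_cv = 0.1)
  args[names(list(...))] <- list(...)
  do.call(sample_spec, args)
}

# Geometry/problem-size template used by the simulation-heavy tests.
sim_template <- list(n_images = 2L, cells_per_image = 16L,
                     image_shape = c(96L, 96L))

# Constant-valued channel image.
const_image <- function(value, shape = c(8L, 8L), channel = "green",
                        bit_depth = 16L, field_id = "f", sample_id = "s") {
  channel_image(matrix(as.integer(value), shape[1], shape[2]),
                channel = channel, bit_depth = bit_depth,
                field_id = field_id, sample_id = sample_id)
}

# Independent two-sided Fisher oracle: exhaustive enumeration of the
# hypergeometric distribution at fixed margins via log-binomials (lchoose),
# summing probabilities of all tables no more probable than the observed
# one. Uses no part of stats::fisher.test.
fisher_enum_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); N <- sum(tab)
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == N) return(1)
  a <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(N, c1)
  p <- exp(logp)
  p_obs <- p[a == tab[1, 1]]
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# Pooled two-sample t by the textbook closed form (independent of t.test).
pooled_t_closed_form <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = n1 + n2 - 2, p = 2 * pt(-abs(t), n1 + n2 - 2))
}

# Construct a raw vector with EXACT (n, mean, sd).
vector_with_summaries <- function(n, m, s, seed = 1) {
  raw <- withr::with_seed(seed, rnorm(n))
  z <- (raw - mean(raw)) / sd(raw)
  m + s * z
}
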