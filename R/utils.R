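#' @importFrom stats rnorm sd pt pf var aggregate
#' @importFrom utils read.csv write.csv packageVersion
NULL

#' Derive a reproducible sub-seed from a master seed and string tags
#'
#' Streams for individual samples and images are derived by stable string
#' hashing so that regenerating any one field never depends on how many
#' other fields were generated before it (order-insensitivity).
#'
#' @param seed master integer seed
#' @param ... tags (sample id, image index, stage name) coerced to character
#' @return an integer in [0, 2^31 - 2], usable with [set.seed()]
#' @keywords internal
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  tags <- paste(vapply(list(...), as.character, character(1)), collapse = "\r")
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(tags)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# Draw from Normal(mean, sd) truncated to (0, Inf) by resampling.
# sd = 0 degenerates to the mean (which must itself be positive when
# positivity is required by the caller).
rnorm_trunc0 <- function(n, mean, sd) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  bad <- which(x <= 0)
  guard <- 0L
  while (length(bad) > 0L) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= 0]
    guard <- guard + 1L
    if (guard > 10000L) stop("truncated-normal resampling did not converge; ",
                             "mean/sd (", mean, "/", sd, ") leave almost no mass above 0")
  }
  x
}

assert_scalar_num <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("'", name, "' must be a single finite number", call. = FALSE)
  }
  if (strict_min && x <= min) stop("'", name, "' must be > ", min, call. = FALSE)
  if (!strict_min && x < min) stop("'", name, "' must be >= ", min, call. = FALSE)
  invisible(x)
}
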