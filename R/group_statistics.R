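group_comparison <- function(method, statistic, df, p_value, n_a, n_b = NA_integer_,
                             group_a = "", group_b = "", df2 = NA_real_) {
  data.frame(group_a = group_a, group_b = group_b, method = method,
             statistic = statistic, df = df, df2 = df2,
             p_value = p_value, n_a = n_a, n_b = n_b,
             stringsAsFactors = FALSE)
}

as_ratio_vector <- function(x) {
  if (is.data.frame(x)) {
    col <- intersect(c("mean_ratio", "ratio"), names(x))[1]
    if (is.na(col)) stop("data.frame input needs a 'mean_ratio' or 'ratio' column")
    x <- x[[col]]
  }
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("values must be finite")
  x
}

#' Two-sample t-test on raw ratio values
#'
#' Compares two groups of sample mean ratios (or any two numeric vectors).
#' `t_pooled` is the classic Student test with the common-variance estimate
#' and `n_a + n_b - 2` degrees of freedom; `t_welch` uses the Satterthwaite
#' approximation. Two-sided throughout.
#'
#' @param a,b numeric vectors, or data.frames with a `mean_ratio` column
#' @param method `"t_pooled"` (default) or `"t_welch"`
#' @param group_a,group_b labels recorded in the result
#' @return one-row comparison data.frame (`statistic`, `df`, `p_value`, ...)
#' @export
t_test_groups <- function(a, b, method = c("t_pooled", "t_welch"),
                          group_a = "A", group_b = "B") {
  method <- match.arg(method)
  a <- as_ratio_vector(a); b <- as_ratio_vector(b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 values")
  }
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(group_comparison(method, 0, length(a) + length(b) - 2, 1,
                              length(a), length(b), group_a, group_b))
    }
    warning("both groups have zero variance with different means; p = 0")
    return(group_comparison(method, Inf, length(a) + length(b) - 2, 0,
                            length(a), length(b), group_a, group_b))
  }
  tt <- stats::t.test(a, b, var.equal = (method == "t_pooled"))
  group_comparison(method, unname(tt$statistic), unname(tt$parameter),
                   tt$p.value, length(a), length(b), group_a, group_b)
}

#' Two-sample t-test from summary statistics
#'
#' Computes the pooled (Student) or Welch t-test directly from
#' `(n, mean, sd)` triples, so published group summaries ("M.R plus/minus
#' SD") can be tested without the raw per-sample values. The result is
#' identical to [t_test_groups()] applied to any raw data having exactly
#' those summaries.
#'
#' @param n1,m1,s1 size, mean and SD of group 1
#' @param n2,m2,s2 size, mean and SD of group 2
#' @param method `"t_pooled"` (default) or `"t_welch"`
#' @param group_a,group_b labels recorded in the result
#' @return one-row comparison data.frame
#' @export
t_test_from_summaries <- function(n1, m1, s1, n2, m2, s2,
                                  method = c("t_pooled", "t_welch"),
                                  group_a = "A", group_b = "B") {
  method <- match.arg(method)
  stopifnot(n1 >= 2L, n2 >= 2L, s1 >= 0, s2 >= 0)
  if (s1 == 0 && s2 == 0) {
    if (m1 == m2) {
      return(group_comparison(method, 0, n1 + n2 - 2, 1, n1, n2, group_a, group_b))
    }
    warning("both SDs are zero with different means; statistic infinite, p = 0")
    return(group_comparison(method, Inf, n1 + n2 - 2, 0, n1, n2, group_a, group_b))
  }
  if (method == "t_pooled") {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  p <- 2 * pt(-abs(t), df)
  group_comparison(method, t, df, p, n1, n2, group_a, group_b)
}

#' One-way analysis of variance over k groups
#'
#' @param groups list of numeric vectors (each of length >= 2), optionally
#'   named with group labels
#' @return one-row comparison data.frame with the F statistic, `df`
#'   (between), `df2` (within) and p value
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  groups <- lapply(groups, as_ratio_vector)
  ns <- lengths(groups)
  if (any(ns < 2L)) stop("every group needs at least 2 values")
  values <- unlist(groups, use.names = FALSE)
  if (var(values) == 0) stop("degenerate: total variance is zero")
  fac <- factor(rep(seq_along(groups), ns))
  ow <- stats::oneway.test(values ~ fac, var.equal = TRUE)
  labs <- names(groups)
  group_comparison("anova", unname(ow$statistic),
                   unname(ow$parameter["num df"]), ow$p.value,
                   n_a = sum(ns), df2 = unname(ow$parameter["denom df"]),
                   group_a = if (is.null(labs)) "" else paste(labs, collapse = "|"))
}

check_table <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts != round(counts)) || any(counts < 0)) {
    stop("contingency counts must be nonnegative integers")
  }
  if (nrow(counts) < 2L || ncol(counts) < 2L) stop("table must be at least 2x2")
  storage.mode(counts) <- "integer"
  counts
}

#' Fisher's exact test on a 2x2 contingency table
#'
#' Two-sided p value obtained by summing, at fixed margins, the
#' hypergeometric probabilities of all tables no more probable than the
#' observed one. A table with a zero margin admits only one configuration,
#' so p = 1.
#'
#' @param counts 2x2 matrix of nonnegative integer counts
#' @return one-row comparison data.frame; `statistic` is the conditional
#'   MLE odds ratio
#' @export
fisher_exact <- function(counts) {
  counts <- check_table(counts)
  if (nrow(counts) != 2L || ncol(counts) != 2L) {
    stop("fisher_exact handles 2x2 tables; use chi_square() for larger tables")
  }
  if (any(rowSums(counts) == 0L) || any(colSums(counts) == 0L)) {
    return(group_comparison("fisher_exact", NA_real_, NA_real_, 1,
                            n_a = sum(counts)))
  }
  ft <- stats::fisher.test(counts)
  group_comparison("fisher_exact", unname(ft$estimate), NA_real_, ft$p.value,
                   n_a = sum(counts))
}

#' Pearson chi-square test on an r x c contingency table
#'
#' No continuity correction is applied. When any expected count falls
#' below 5 a warning recommends [fisher_exact()] instead.
#'
#' @param counts matrix of nonnegative integer counts, at least 2x2
#' @return one-row comparison data.frame with the Pearson statistic,
#'   `df = (r-1)(c-1)` and p value
#' @export
chi_square <- function(counts) {
  counts <- check_table(counts)
  if (any(rowSums(counts) == 0L) || any(colSums(counts) == 0L)) {
    stop("zero row or column sum: expected counts are undefined")
  }
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected < 5)) {
    warning("some expected counts are below 5; consider fisher_exact() for 2x2 tables")
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  group_comparison("chi_square", unname(ct$statistic), unname(ct$parameter),
                   ct$p.value, n_a = sum(counts))
}
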