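# Nonparametric group comparisons matching the study's statistical layer:
# Wilcoxon signed-rank for paired designs, Mann-Whitney U for unpaired ones,
# and a rank correlation for the SD-vs-irregularity relationship.
#
# At the study's sample sizes (6-10 animals per arm) large-sample
# approximations are inaccurate, so p-values are computed by full enumeration
# of the permutation null whenever feasible; the method actually used is
# always recorded in the result.

new_comparison <- function(test_name, statistic, p_value, n1, n2, method,
                           alpha, degenerate = FALSE, n_zero_dropped = 0L) {
  p_value <- min(max(p_value, 0), 1)
  structure(list(test_name = test_name, statistic = statistic,
                 p_value = p_value, n1 = n1, n2 = n2, method = method,
                 alpha = alpha, significant = p_value < alpha,
                 degenerate = degenerate, n_zero_dropped = n_zero_dropped),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %g, p = %.5g (%s)%s%s\n",
              x$test_name, x$statistic, x$p_value, x$method,
              if (x$significant) sprintf(" * significant at %g", x$alpha)
              else "",
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' @export
as.data.frame.comparison_result <- function(x, ...) {
  data.frame(test_name = x$test_name, statistic = x$statistic,
             p_value = x$p_value, n1 = x$n1, n2 = x$n2, method = x$method,
             significant = x$significant, degenerate = x$degenerate,
             stringsAsFactors = FALSE)
}

# signed-rank statistic V over all 2^n sign assignments of midranks r
signed_rank_exact_p <- function(r, v_obs) {
  n <- length(r)
  m <- 2^n
  masks <- 0:(m - 1L)
  v_all <- numeric(m)
  for (j in seq_len(n))
    v_all <- v_all + r[j] * (bitwAnd(masks, bitwShiftL(1L, j - 1L)) > 0L)
  mu <- sum(r) / 2
  mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-9)
}

#' Paired comparison (Wilcoxon signed-rank test)
#'
#' Two-sided signed-rank test of `after - before`.  Zero differences are
#' dropped (Wilcoxon's convention; the count is reported).  For n <= 15
#' usable pairs the p-value is exact, by enumeration of all `2^n` sign
#' assignments of the (mid)ranks of `|differences|` - ties in magnitude are
#' handled by the enumeration itself.  Larger samples use the normal
#' approximation with tie correction and continuity correction.
#'
#' @param before,after paired measurement vectors of equal length.
#' @param alpha significance level (study convention 0.05).
#' @param exact_max_n largest n for which the exact null is enumerated.
#' @return A `comparison_result` with the statistic V (sum of ranks of
#'   positive differences), p-value, method, and significance flag.  If every
#'   difference is zero the result is degenerate with p = 1.
#' @export
paired_compare <- function(before, after, alpha = 0.05, exact_max_n = 15L) {
  if (length(before) != length(after))
    data_error("before and after must have equal length")
  if (!is.numeric(before) || !is.numeric(after) ||
      anyNA(before) || anyNA(after))
    data_error("paired samples must be numeric with no missing values")
  d <- after - before
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(new_comparison("wilcoxon_signed_rank", statistic = 0, p_value = 1,
                          n1 = n_zero, n2 = n_zero, method = "degenerate",
                          alpha = alpha, degenerate = TRUE,
                          n_zero_dropped = n_zero))
  if (n < 3L)
    data_error(sprintf(
      "need >= 3 non-zero differences, have %d (after dropping %d zero(s))",
      n, n_zero))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_max_n) {
    p <- signed_rank_exact_p(r, v)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- v - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
    p <- 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE))
    method <- "normal_approx"
  }
  new_comparison("wilcoxon_signed_rank", statistic = v, p_value = p,
                 n1 = n, n2 = n, method = method, alpha = alpha,
                 n_zero_dropped = n_zero)
}

# U statistic over all C(n1+n2, n1) group labelings
mann_whitney_exact_p <- function(rk, n1, u_obs) {
  N <- length(rk)
  combos <- combn(N, n1)
  u_all <- colSums(matrix(rk[combos], nrow = n1)) - n1 * (n1 + 1) / 2
  mu <- n1 * (N - n1) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

#' Unpaired comparison (Mann-Whitney U test)
#'
#' Two-sided rank-sum test between independent groups.  When
#' `n1 + n2 <= 16` and the combined sample has no tied values the p-value is
#' exact, by enumeration of all `choose(n1 + n2, n1)` group labelings;
#' otherwise the tie-corrected normal approximation (with continuity
#' correction) is used.
#'
#' @param group_a,group_b measurement vectors, each of length >= 3.
#' @param alpha significance level.
#' @param exact_max_total largest combined size for which the exact null is
#'   enumerated.
#' @return A `comparison_result` with the statistic U (for `group_a`),
#'   p-value, method and significance flag.
#' @export
unpaired_compare <- function(group_a, group_b, alpha = 0.05,
                             exact_max_total = 16L) {
  if (length(group_a) == 0L || length(group_b) == 0L)
    data_error("both groups must be non-empty")
  if (length(group_a) < 3L || length(group_b) < 3L)
    data_error("both groups need n >= 3")
  if (!is.numeric(group_a) || !is.numeric(group_b) ||
      anyNA(group_a) || anyNA(group_b))
    data_error("group samples must be numeric with no missing values")
  n1 <- length(group_a); n2 <- length(group_b); N <- n1 + n2
  comb <- c(group_a, group_b)
  rk <- rank(comb)
  u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(comb) > 0L
  if (N <= exact_max_total && !has_ties) {
    p <- mann_whitney_exact_p(rk, n1, u)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(rk)
    sigma2 <- (n1 * n2 / 12) *
      ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0)
      return(new_comparison("mann_whitney_u", statistic = u, p_value = 1,
                            n1 = n1, n2 = n2, method = "degenerate",
                            alpha = alpha, degenerate = TRUE))
    z <- u - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE))
    method <- "normal_approx"
  }
  new_comparison("mann_whitney_u", statistic = u, p_value = p,
                 n1 = n1, n2 = n2, method = method, alpha = alpha)
}

#' Rank correlation between heart-rate SD and irregularity score
#'
#' Spearman rank correlation with a two-sided p-value, for the
#' across-animals association between the SD of heart rate and the mean
#' irregularity score.  The coefficient choice is recorded in the result.
#'
#' @param hr_sds,is_means equal-length numeric vectors, n >= 3.
#' @return List with `coefficient`, `p_value`, `method = "spearman"`, `n`,
#'   and a `degenerate` flag (TRUE, with NA coefficient, when either input is
#'   constant).
#' @export
sd_is_correlation <- function(hr_sds, is_means) {
  if (length(hr_sds) != length(is_means))
    data_error("inputs must have equal length")
  n <- length(hr_sds)
  if (n < 3L) data_error("need n >= 3 pairs")
  if (anyNA(hr_sds) || anyNA(is_means))
    data_error("inputs must not contain missing values")
  if (length(unique(hr_sds)) == 1L || length(unique(is_means)) == 1L)
    return(list(coefficient = NA_real_, p_value = NA_real_,
                method = "spearman", n = n, degenerate = TRUE))
  ct <- suppressWarnings(cor.test(hr_sds, is_means, method = "spearman"))
  list(coefficient = unname(ct$estimate), p_value = ct$p.value,
       method = "spearman", n = n, degenerate = FALSE)
}
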