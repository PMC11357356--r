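# Contingency-table and rank-based statistics, implemented from first
# principles so every formula is auditable. Results are broom-style one-row
# tibbles. Base R's chisq.test/wilcox.test/kruskal.test are deliberately not
# called here; the test suite uses them as independent cross-checks.

#' Pearson chi-square test for a 2x2 table
#'
#' Uncorrected Pearson chi-square for a 2x2 contingency table (rows =
#' groups, columns = e.g. roller/non-roller):
#' `chi2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, df = 1. No Yates
#' continuity correction is applied — the convention in this literature's
#' group-proportion comparisons.
#'
#' @param a,b,c,d Non-negative integer counts, row-wise
#'   (`a b` on top, `c d` below). Alternatively pass a 2x2 matrix as `a`.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `n`, `method`.
#' @examples
#' chi2_2x2(54, 27, 29, 90)   # rollers/non-rollers in two groups
#' @export
chi2_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) { d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1] }
  counts <- c(a, b, c, d)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    abort("counts must be non-negative integers")
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) abort("all table margins must be positive")
  N <- sum(counts)
  stat <- N * (a * d - b * c)^2 / prod(margins)
  tibble::tibble(statistic = stat, df = 1L,
                 p_value = pchisq(stat, 1, lower.tail = FALSE),
                 n = N, method = "Pearson chi-square (no continuity correction)")
}

# Exact two-sided Mann-Whitney p by complete enumeration of group
# assignments (ties handled through midranks).
mwu_exact_p <- function(ranks, n1, u_obs) {
  n <- length(ranks)
  sets <- utils::combn(n, n1)
  u_all <- apply(sets, 2, function(idx) {
    u1 <- sum(ranks[idx]) - n1 * (n1 + 1) / 2
    min(u1, n1 * (n - n1) - u1)
  })
  mean(u_all <= u_obs + 1e-9)
}

#' Mann-Whitney U test
#'
#' Rank-sum test of two independent samples with midranks for ties. Reports
#' `U = min(U1, U2)`. The two-sided p-value is exact (complete enumeration of
#' group assignments) when `n1 + n2 <= exact_max`, otherwise a normal
#' approximation with tie-corrected variance.
#'
#' @param x,y Numeric samples.
#' @param exact_max Largest combined sample size for exact enumeration.
#' @return One-row tibble: `statistic` (U), `p_value`, `n1`, `n2`, `method`.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))   # exact p = 1/3
#' @export
mann_whitney_u <- function(x, y, exact_max = 12) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) abort("both samples must be non-empty")
  ranks <- rank(c(x, y))
  r1 <- sum(ranks[seq_len(n1)])
  u1 <- r1 - n1 * (n1 + 1) / 2
  u <- min(u1, n1 * n2 - u1)
  if (n1 + n2 <= exact_max) {
    p <- mwu_exact_p(ranks, n1, u)
    method <- "Mann-Whitney U (exact enumeration)"
  } else {
    N <- n1 + n2
    ties <- table(ranks)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- max(abs(u1 - n1 * n2 / 2) - 0.5, 0) / sqrt(sigma2)  # continuity corr.
      p <- min(1, 2 * pnorm(-z))
    }
    method <- "Mann-Whitney U (normal approximation, tie- and continuity-corrected)"
  }
  tibble::tibble(statistic = u, p_value = p, n1 = n1, n2 = n2, method = method)
}

#' Kruskal-Wallis rank test
#'
#' H statistic over k groups with tie correction; p from the chi-square
#' distribution with k - 1 df. If every observation is identical the tie
#' correction is degenerate and H is reported as 0 with a warning.
#'
#' @param groups List of numeric samples (>= 2 non-empty groups).
#' @return One-row tibble: `statistic` (H), `df`, `p_value`, `n`, `method`.
#' @examples
#' kruskal_wallis(list(rnorm(10), rnorm(10, 1), rnorm(10, 2)))
#' @export
kruskal_wallis <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2 || any(lengths(groups) == 0))
    abort("need >= 2 non-empty groups")
  all_x <- unlist(groups)
  N <- length(all_x)
  ranks <- rank(all_x)
  g <- rep(seq_along(groups), lengths(groups))
  rsum <- tapply(ranks, g, sum)
  H <- 12 / (N * (N + 1)) * sum(rsum^2 / lengths(groups)) - 3 * (N + 1)
  ties <- table(ranks)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C <= 0) {
    warn("all observations tied; H is degenerate and reported as 0")
    H <- 0
  } else {
    H <- H / C
  }
  df <- length(groups) - 1L
  tibble::tibble(statistic = H, df = df,
                 p_value = pchisq(H, df, lower.tail = FALSE),
                 n = N, method = "Kruskal-Wallis (tie-corrected)")
}

#' Bonferroni correction
#'
#' @param p_values Numeric p-values.
#' @param m Number of comparisons (defaults to `length(p_values)`; must be at
#'   least that).
#' @return Adjusted p-values, `min(1, m * p)`.
#' @examples
#' bonferroni(c(0.01, 0.5), m = 4)
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (m < length(p_values)) abort("m must be >= number of p-values")
  pmin(1, m * p_values)
}

#' Cohen's d effect size
#'
#' Standardized mean difference with the pooled (n-1 weighted) SD.
#'
#' @param x,y Numeric samples, each with >= 2 values.
#' @return Numeric effect size `(mean(x) - mean(y)) / s_pooled`.
#' @examples
#' cohens_d(rnorm(50, 1), rnorm(50, 0))
#' @export
cohens_d <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) abort("each sample needs >= 2 values")
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (sp2 <= 0) abort("pooled SD is zero")
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Wilson score interval for a proportion
#'
#' @param k Successes (0 <= k <= n).
#' @param n Trials (> 0).
#' @param level Confidence level.
#' @return Numeric `c(lower, upper)`.
#' @examples
#' wilson_ci(54, 81)
#' @export
wilson_ci <- function(k, n, level = 0.95) {
  if (n <= 0) abort("n must be positive")
  if (k < 0 || k > n) abort("k must be in [0, n]")
  z <- qnorm(1 - (1 - level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, center - half), min(1, center + half))
}

#' Normality screen
#'
#' Shapiro-Wilk screen used to decide between parametric and nonparametric
#' branches; the pipeline defaults to the nonparametric branch regardless,
#' and this is advisory.
#'
#' @param x Numeric sample (3-5000 values).
#' @param alpha Significance level.
#' @return One-row tibble: `statistic` (W), `p_value`, `normal` (logical).
#' @export
normality_check <- function(x, alpha = 0.05) {
  res <- stats::shapiro.test(x)
  tibble::tibble(statistic = unname(res$statistic), p_value = res$p.value,
                 normal = res$p.value >= alpha)
}
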