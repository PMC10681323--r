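#' Nonparametric test toolkit
#'
#' Thin, uniformly-shaped wrappers around the nonparametric tests the
#' pipeline reports, each returning a one-row tibble with `method`,
#' `statistic`, `df` and `p_value` so results drop straight into summary
#' tables. Standard distributions are delegated to the stock routines
#' (`chisq.test`, `wilcox.test`, `kruskal.test`, `fisher.test`); the Dunn
#' post-hoc and the tie-corrected Spearman statistic are computed here.
#'
#' @name shark_stats
NULL

#' Chi-squared goodness-of-fit test
#'
#' @param observed Non-negative integer counts.
#' @param expected_prop Expected proportions (default uniform); must sum
#'   to 1 with no zero cell.
#' @return One-row tibble `method`, `statistic`, `df`, `p_value`.
#' @examples
#' chi_square_gof(c(40, 17, 9)) # statistic 23.545, df 2
#' @rdname shark_stats
#' @export
chi_square_gof <- function(observed,
                           expected_prop = rep(1 / length(observed), length(observed))) {
  if (any(observed < 0)) abort("Counts must be non-negative.")
  if (abs(sum(expected_prop) - 1) > 1e-8) abort("Expected proportions must sum to 1.")
  if (any(expected_prop <= 0)) abort("Expected proportions must be positive.")
  ht <- stats::chisq.test(observed, p = expected_prop)
  tibble(method = "Chi-squared goodness of fit",
         statistic = unname(ht$statistic), df = as.integer(ht$parameter),
         p_value = ht$p.value)
}

#' Tie-corrected Spearman rank correlation
#'
#' Computes rho as the Pearson correlation of mid-ranks (the tie-corrected
#' estimate), reports the companion `S` statistic on the same scale as the
#' classical sum of squared rank differences, `S = (1 - rho) n (n^2 - 1) / 6`
#' (non-integer in the presence of ties), and a two-sided p-value from the
#' t approximation `t = rho sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param x,y Equal-length numeric vectors, n >= 3, non-constant.
#' @return One-row tibble with `statistic` = S and `estimate` = rho.
#' @rdname shark_stats
#' @export
spearman_rank <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("Need at least 3 paired observations.")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) abort("Constant vector: rho undefined.")
  rho <- cor(rank(x), rank(y))
  s <- (1 - rho) * n * (n^2 - 1) / 6
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  tibble(method = "Spearman rank correlation (tie-corrected)",
         statistic = s, df = NA_integer_,
         p_value = 2 * pt(-abs(tval), df = n - 2),
         estimate = rho)
}

#' Mann-Whitney U (Wilcoxon rank-sum) test
#'
#' Two-sided two-sample rank test. The statistic is reported in the
#' rank-sum `W` convention of `wilcox.test` (number of pairs `(a, b)` with
#' `a > b`, counting ties as half); the classical `U` of sample `a` equals
#' this `W`. Exact enumeration is used automatically for small untied
#' samples, the tie-corrected normal approximation otherwise.
#'
#' @param a,b Non-empty numeric vectors.
#' @return One-row tibble; `statistic` is W.
#' @rdname shark_stats
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) abort("Both samples must be non-empty.")
  ht <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided",
                                            correct = TRUE))
  tibble(method = "Mann-Whitney U test",
         statistic = unname(ht$statistic), df = NA_integer_,
         p_value = min(1, ht$p.value))
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic compared to a chi-squared distribution with
#' k - 1 degrees of freedom.
#'
#' @param groups List of numeric vectors (>= 2 non-empty groups).
#' @return One-row tibble.
#' @rdname shark_stats
#' @export
kruskal_wallis <- function(groups) {
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2) abort("Need at least two non-empty groups.")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- stats::kruskal.test(x, g)
  stat <- unname(ht$statistic)
  if (is.nan(stat)) stat <- 0 # all values tied across all groups
  tibble(method = "Kruskal-Wallis rank sum test",
         statistic = stat, df = as.integer(ht$parameter),
         p_value = if (is.nan(unname(ht$statistic))) 1 else ht$p.value)
}

#' Dunn post-hoc test
#'
#' Pairwise follow-up to a Kruskal-Wallis test: for each pair of groups the
#' standardised difference of mean pooled mid-ranks,
#' `Z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))`, with the
#' tie term `T = sum(t^3 - t) / (12 (N - 1))`, and a two-sided normal
#' p-value per pair, optionally Bonferroni-adjusted. Empty groups are
#' dropped with a warning.
#'
#' @param groups Named (or unnamed) list of numeric vectors.
#' @param adjustment `"none"` (default) or `"bonferroni"`.
#' @return Tibble with one row per pair: `group1`, `group2`, `z`,
#'   `p_value`, `p_adjusted`.
#' @rdname shark_stats
#' @export
dunn_posthoc <- function(groups, adjustment = c("none", "bonferroni")) {
  adjustment <- match.arg(adjustment)
  if (is.null(names(groups))) names(groups) <- as.character(seq_along(groups))
  empty <- lengths(groups) == 0
  if (any(empty)) {
    warn(sprintf("Dropping %d empty group(s): %s", sum(empty),
                 paste(names(groups)[empty], collapse = ", ")))
    groups <- groups[!empty]
  }
  if (length(groups) < 2) abort("Need at least two non-empty groups.")
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  r <- rank(x)
  n_tot <- length(x)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n_tot - 1))
  rbar <- tapply(r, g, mean)
  n_g <- tapply(r, g, length)
  pairs <- utils::combn(names(groups), 2)
  z <- vapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    sigma <- sqrt((n_tot * (n_tot + 1) / 12 - tie_term) * (1 / n_g[[i]] + 1 / n_g[[j]]))
    if (sigma == 0) 0 else (rbar[[i]] - rbar[[j]]) / sigma
  }, numeric(1))
  p <- 2 * pnorm(-abs(z))
  m <- length(z)
  tibble(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p_value = p,
         p_adjusted = if (adjustment == "bonferroni") pmin(1, m * p) else p)
}

#' Fisher exact probability test
#'
#' Exact test of independence for small 2 x k contingency tables (k of 2 or
#' 3), by full enumeration of tables with the observed margins.
#'
#' @param tab Matrix of non-negative integer counts with 2 rows and 2-3
#'   columns.
#' @return One-row tibble (`statistic` is `NA`: the test has no single
#'   statistic).
#' @rdname shark_stats
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) != 2 || !ncol(tab) %in% 2:3) {
    abort("Expected a 2 x 2 or 2 x 3 count table.")
  }
  if (any(tab < 0) || any(tab != round(tab))) abort("Counts must be non-negative integers.")
  ht <- stats::fisher.test(tab)
  tibble(method = "Fisher exact probability test",
         statistic = NA_real_, df = NA_integer_, p_value = ht$p.value)
}
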