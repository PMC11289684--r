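# Core statistical primitives of the benchmarked rankers. These are the
# quantities the benchmark audits, so they are implemented here explicitly;
# tests cross-check them against independent enumeration oracles and against
# stats::fisher.test / stats::wilcox.test.

#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test. `"greater"` returns the upper tail
#' `P[X >= a]` given the table margins; `"two.sided"` sums the point
#' probabilities of all tables in the support whose probability does not
#' exceed that of the observed table (with the standard `1 + 1e-7` relative
#' tolerance against floating-point ties).
#'
#' @param table A [contingency_table()], or `a` when the four cells are
#'   given separately.
#' @param b,c,d Remaining cells when not using a `contingency_table`.
#' @param alternative `"greater"` or `"two.sided"`.
#' @return The p-value.
#' @examples
#' fisher_exact(contingency_table(5, 5, 5, 85), alternative = "greater")
#' @export
fisher_exact <- function(table, b = NULL, c = NULL, d = NULL,
                         alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (inherits(table, "contingency_table")) {
    a <- table$a; b <- table$b; c <- table$c; d <- table$d
  } else {
    a <- table
  }
  m <- a + c                      # target-set size
  n <- b + d                      # non-target size
  k <- a + b                      # query size
  if (m == 0 || n == 0 || k == 0 || (m + n - k) == 0) return(1)
  support <- max(0L, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  if (alternative == "greater") {
    p <- sum(probs[support >= a])
  } else {
    p <- sum(probs[probs <= probs[support == a] * (1 + 1e-7)])
  }
  min(max(p, 0), 1)
}

# vectorized one-sided ("greater") hypergeometric p for ranker hot paths:
# a successes in query of size k, target size m, background size N
phyper_greater <- function(a, m, N, k) {
  phyper(a - 1, m, N - m, k, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR correction with monotonicity enforcement, in the
#' input order.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return q-values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Stouffer's Z-score combination
#'
#' Combines one-sided p-values as `Z_i = qnorm(1 - p_i)`,
#' `Z_c = sum(Z_i) / sqrt(I)`, `p_c = 1 - pnorm(Z_c)`.
#'
#' @param pvalues One-sided p-values; clipped to `[1e-15, 1 - 1e-15]`.
#' @return A list with `Z_c` and `p_c` (and the per-list `Z_i`).
#' @examples
#' stouffer_combine(c(0.0228, 0.0228))  # Z_c ~ 2.83, p_c ~ 0.0023
#' @export
stouffer_combine <- function(pvalues) {
  if (length(pvalues) == 0) stop("stouffer_combine needs at least one p-value")
  p <- pmin(pmax(pvalues, 1e-15), 1 - 1e-15)
  z <- qnorm(1 - p)
  zc <- sum(z) / sqrt(length(z))
  list(Z_i = z, Z_c = zc, p_c = 1 - pnorm(zc))
}

#' Cauchy combination of p-values
#'
#' Aggregates possibly dependent p-values through the tangent transform:
#' `T = sum(w_i * tan((0.5 - p_i) * pi))` with weights defaulting to `1/k`,
#' combined p `= 0.5 - atan(T) / pi`.
#'
#' @param pvalues P-values; clipped to `[clip, 1 - clip]`.
#' @param weights Optional non-negative weights; normalized to sum 1.
#' @param clip Clipping bound (default `1e-15`). Rankers that need to
#'   discriminate between extremely significant datasets lower it, since
#'   the tangent transform is numerically stable down to the double range.
#' @return The combined p-value, strictly inside (0, 1).
#' @export
cauchy_combine <- function(pvalues, weights = NULL, clip = 1e-15) {
  k <- length(pvalues)
  if (k == 0) stop("cauchy_combine needs at least one p-value")
  p <- pmin(pmax(pvalues, clip), 1 - 1e-15)
  if (is.null(weights)) weights <- rep(1 / k, k)
  if (length(weights) != k || any(weights < 0))
    stop("weights must be non-negative and match the p-values in length")
  weights <- weights / sum(weights)
  stat <- sum(weights * tan((0.5 - p) * pi))
  0.5 - atan(stat) / pi
}

# One-sided Wilcoxon rank-sum p-value: exact distribution when both groups
# are small and tie-free (via stats::wilcox.test), tie-corrected normal
# approximation otherwise (computed directly so large-sample calls stay
# cheap and p-values do not underflow before pnorm does). No continuity
# correction: the plain normal tail behaves like a mid-p, which keeps
# qnorm(1 - p) unbiased under the null - essential when many such p-values
# are combined by Stouffer's method. alternative = "less" means x tends to
# have SMALLER values.
rank_sum_test <- function(x, y, alternative = c("less", "greater"),
                          exact_max = 12L, log_p = FALSE) {
  alternative <- match.arg(alternative)
  m <- length(x)
  n <- length(y)
  if (m <= exact_max && n <= exact_max && !anyDuplicated(c(x, y))) {
    res <- suppressWarnings(
      wilcox.test(x, y, alternative = alternative, exact = TRUE))
    p <- unname(res$p.value)
    return(if (log_p) log(p) else p)
  }
  r <- rank(c(x, y))
  W <- sum(r[seq_len(m)]) - m * (m + 1) / 2     # Mann-Whitney U of x
  mu <- m * n / 2
  cnt <- tabulate(match(r, unique(r)))
  sigma2 <- (m * n / 12) *
    ((m + n + 1) - sum(cnt^3 - cnt) / ((m + n) * (m + n - 1)))
  sigma <- sqrt(max(sigma2, 1e-12))
  z <- if (alternative == "greater") -(W - mu) / sigma else (W - mu) / sigma
  pnorm(z, log.p = log_p)
}

# Cauchy combination on the log scale: identical to cauchy_combine() for
# moderate p but keeps astronomically small p-values distinguishable by
# switching to the asymptotic tan((0.5 - p) * pi) ~ 1/(pi * p) for tiny p.
# Returns log(p_c).
cauchy_combine_log <- function(log_p, weights = NULL) {
  k <- length(log_p)
  if (k == 0) stop("cauchy_combine_log needs at least one p-value")
  if (is.null(weights)) weights <- rep(1 / k, k)
  weights <- weights / sum(weights)
  lp <- pmin(log_p, log(1 - 1e-15))
  tiny <- lp < log(1e-12)
  direct <- if (all(tiny)) 0 else
    sum(weights[!tiny] * tan((0.5 - exp(lp[!tiny])) * pi))
  if (any(tiny)) {
    lt <- log(weights[tiny]) - log(pi) - lp[tiny]
    M <- max(lt)
    log_t_tiny <- M + log(sum(exp(lt - M)))
    if (log_t_tiny > 40) return(-log(pi) - log_t_tiny)
    stat <- exp(log_t_tiny) + direct
  } else {
    stat <- direct
  }
  if (stat > 1e12) return(-log(pi) - log(stat))
  log(max(0.5 - atan(stat) / pi, 5e-324))
}

#' Rank-based AUC (Mann-Whitney with tie correction)
#'
#' Probability that a randomly chosen positive outscores a randomly chosen
#' negative, ties counting one half.
#'
#' @param labels Logical (or 0/1) class labels; both classes must be present.
#' @param scores Numeric scores, higher = more positive.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(labels, scores) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop("auc requires both classes to be present")
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
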