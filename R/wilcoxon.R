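# Wilcoxon tests with a fully declared policy:
#   * signed rank: zero differences dropped, mid-ranks for ties, exact null
#     distribution (shift algorithm over sign assignments) for n <= 25, else
#     normal approximation with tie correction and continuity correction;
#   * rank sum: mid-ranks, exact distribution (subset-sum DP) when the pooled
#     sample has <= 25 observations, else corrected normal approximation.
# Mid-ranks can be half-integers, so the exact DP runs on doubled ranks.
# Two-sided p = min(1, 2 * min(lower tail, upper tail)).

exact_signed_rank_p <- function(w, ranks) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  counts <- numeric(total + 1)
  counts[1] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), counts[seq_len(total + 1 - r)])
    counts <- counts + shifted
  }
  w2 <- as.integer(round(2 * w))
  denom <- 2^length(r2)
  lower <- sum(counts[seq_len(w2 + 1)]) / denom
  upper <- sum(counts[seq.int(w2 + 1, total + 1)]) / denom
  min(1, 2 * min(lower, upper))
}

exact_rank_sum_p <- function(w, ranks, n_a) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  # f[k+1, s+1] = number of k-subsets with doubled-rank sum s
  f <- matrix(0, n_a + 1, total + 1)
  f[1, 1] <- 1
  for (r in r2) {
    fk <- f
    f[2:(n_a + 1), (r + 1):(total + 1)] <-
      f[2:(n_a + 1), (r + 1):(total + 1)] + fk[1:n_a, 1:(total + 1 - r)]
  }
  counts <- f[n_a + 1, ]
  denom <- choose(length(r2), n_a)
  w2 <- as.integer(round(2 * w))
  lower <- sum(counts[seq_len(w2 + 1)]) / denom
  upper <- sum(counts[seq.int(w2 + 1, total + 1)]) / denom
  min(1, 2 * min(lower, upper))
}

#' Paired comparison (Wilcoxon signed-rank test)
#'
#' @param a,b paired numeric vectors of equal length.
#' @param exact_limit use the exact null distribution when the number of
#'   nonzero differences is at most this (default 25).
#' @return list with `statistic` (sum of positive-difference ranks),
#'   `p_value`, `n_effective` (nonzero differences) and `method`.
#' @export
compare_paired <- function(a, b, exact_limit = 25L) {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  d <- a - b
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all paired differences are zero; test is degenerate, reporting p = 1")
    return(list(statistic = 0, p_value = 1, n_effective = 0L,
                method = "wilcoxon signed-rank (degenerate)"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_limit) {
    p <- exact_signed_rank_p(w, r)
    method <- "wilcoxon signed-rank (exact, mid-ranks, zeros dropped)"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "wilcoxon signed-rank (normal approximation, continuity corrected)"
  }
  list(statistic = w, p_value = p, n_effective = n, method = method)
}

#' Unpaired comparison (Wilcoxon rank-sum test)
#'
#' @param a,b numeric vectors (both nonempty).
#' @param exact_limit use the exact distribution when the pooled size is at
#'   most this (default 25).
#' @return list with `statistic` (rank sum of `a`), `p_value`, `n` and `method`.
#' @export
compare_unpaired <- function(a, b, exact_limit = 25L) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  pooled <- c(a, b)
  r <- rank(pooled)
  n_a <- length(a); n_b <- length(b); N <- n_a + n_b
  w <- sum(r[seq_len(n_a)])
  if (N <= exact_limit) {
    p <- exact_rank_sum_p(w, r, n_a)
    method <- "wilcoxon rank-sum (exact, mid-ranks)"
  } else {
    mu <- n_a * (N + 1) / 2
    ties <- table(r)
    sigma2 <- n_a * n_b / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "wilcoxon rank-sum (normal approximation, continuity corrected)"
  }
  list(statistic = w, p_value = p, n = c(n_a = n_a, n_b = n_b), method = method)
}

#' Two-tier Bonferroni significance flags
#'
#' Reports both the nominal tier (p < alpha) and the corrected tier
#' (p < alpha/m), the way heatmaps in this framework annotate `*` and `**`.
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @param m number of comparisons (e.g. 32 for per-landmark tests, 6 for
#'   per-axis comparisons).
#' @param alpha nominal level (default 0.05).
#' @return data frame with columns `p`, `nominal`, `corrected`.
#' @export
bonferroni <- function(pvals, m, alpha = 0.05) {
  stopifnot(m >= 1)
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  data.frame(p = pvals,
             nominal = !is.na(pvals) & pvals < alpha,
             corrected = !is.na(pvals) & pvals < alpha / m)
}
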