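#' Exact two-sided binomial test p-value
#'
#' Point-probability-ordering two-sided exact binomial test: the p-value is
#' the total probability of all outcomes whose point probability does not
#' exceed that of the observed count. Tail sums are accumulated in log space
#' so that counts in the hundreds of thousands (whole-array sign tallies)
#' are handled without underflow. For `p0 = 0.5` this equals
#' `min(1, 2 * min(lower tail, upper tail))`.
#'
#' @param k observed number of successes.
#' @param n number of trials.
#' @param p0 null success probability, default 0.5.
#' @return two-sided p-value (numeric scalar).
#' @examples
#' binom_two_sided(26, 36)   # directional concordance of 26/36
#' @export
binom_two_sided <- function(k, n, p0 = 0.5) {
  stopifnot(length(k) == 1L, length(n) == 1L, is.finite(k), is.finite(n))
  if (n < 1) stop("binomial test requires n >= 1")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  if (p0 <= 0 || p0 >= 1) {
    if (p0 == 0) return(if (k == 0) 1 else 0)
    if (p0 == 1) return(if (k == n) 1 else 0)
    stop("p0 must be in [0, 1]")
  }
  x <- 0:n
  lf <- dbinom(x, n, p0, log = TRUE)
  # relative tolerance guards ties in point probability against FP noise
  keep <- lf <= lf[k + 1L] + 1e-7
  m <- max(lf[keep])
  min(1, exp(m + log(sum(exp(lf[keep] - m)))))
}

#' One-sample Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test of symmetry about `mu`. Zero differences are
#' dropped. The null distribution of the positive-rank sum is computed
#' exactly (by convolution of the rank generating function) when there are
#' at most `exact_max` nonzero values and no ties in the absolute values;
#' otherwise a normal approximation with continuity and tie correction is
#' used, matching standard signed-rank practice.
#'
#' @param x numeric vector of differences (or values when `mu` given).
#' @param mu null location, default 0.
#' @param exact_max largest n for which the exact distribution is used.
#' @return list with `statistic` (positive-rank sum V), `n` (nonzero count),
#'   `p.value`, and `method` ("exact" or "normal").
#' @export
wilcoxon_signed_rank <- function(x, mu = 0, exact_max = 25L) {
  x <- x[!is.na(x)] - mu
  x <- x[x != 0]
  n <- length(x)
  if (n < 1L) {
    return(list(statistic = NA_real_, n = 0L, p.value = NA_real_,
                method = "none"))
  }
  r <- rank(abs(x))
  v <- sum(r[x > 0])
  ties <- any(duplicated(abs(x)))
  if (n <= exact_max && !ties) {
    # exact null pmf of V: coefficients of prod_i (1 + t^i) / 2^n
    maxv <- n * (n + 1L) / 2L
    pmf <- c(1, rep(0, maxv))
    for (i in seq_len(n)) {
      shifted <- c(rep(0, i), pmf[seq_len(maxv + 1L - i)])
      pmf <- pmf + shifted
    }
    pmf <- pmf / 2^n
    lower <- sum(pmf[seq_len(v + 1L)])        # P(V <= v)
    upper <- sum(pmf[(v + 1L):(maxv + 1L)])   # P(V >= v)
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    mu_v <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (v - mu_v - sign(v - mu_v) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = v, n = n, p.value = p, method = method)
}

#' Paired Wilcoxon signed-rank test
#'
#' Convenience wrapper: signed-rank test on paired differences `x - y`.
#'
#' @param x,y paired numeric vectors.
#' @inheritParams wilcoxon_signed_rank
#' @export
wilcoxon_paired <- function(x, y, exact_max = 25L) {
  stopifnot(length(x) == length(y))
  wilcoxon_signed_rank(x - y, exact_max = exact_max)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up BH adjustment with enforced monotonicity. Missing p-values are
#' excluded from the adjustment (they do not count toward the number of
#' tests) and propagate as missing q-values.
#'
#' @param p numeric vector of p-values in \[0, 1\], NA allowed.
#' @return vector of q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0L) return(q)
  pv <- p[ok]
  if (any(pv < 0 | pv > 1)) stop("p-values must lie in [0, 1]")
  o <- order(pv, decreasing = TRUE)
  adj <- pmin(1, cummin(pv[o] * m / (m:1)))
  q[ok[o]] <- adj
  q
}

#' Two-sided pooled two-proportion z-test
#'
#' Tests equality of two binomial proportions with the pooled-variance
#' normal statistic (no continuity correction).
#'
#' @param k1,n1 successes and trials in group 1.
#' @param k2,n2 successes and trials in group 2.
#' @return list with `z` and `p.value`.
#' @export
two_proportion_test <- function(k1, n1, k2, n2) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  p1 <- k1 / n1
  p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  if (pp <= 0 || pp >= 1) return(list(z = 0, p.value = 1))
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  list(z = z, p.value = min(1, 2 * pnorm(-abs(z))))
}

#' Fisher's exact enrichment test for a 2x2 overlap table
#'
#' Builds the 2x2 table (significant vs background-only) x (overlapping a
#' feature vs not) and applies the two-sided Fisher exact test.
#' `bg_in`/`bg_total` describe the full background including the
#' significant set.
#'
#' @param sig_in significant probes overlapping the feature.
#' @param sig_total significant probes in total.
#' @param bg_in background probes overlapping the feature.
#' @param bg_total background probes in total.
#' @return list with `odds_ratio`, `p.value`, `table`, and `degenerate`
#'   flag (TRUE when a margin is empty, in which case p = 1).
#' @export
fisher_enrichment <- function(sig_in, sig_total, bg_in, bg_total) {
  stopifnot(sig_in <= sig_total, bg_in <= bg_total,
            sig_in <= bg_in, sig_total <= bg_total)
  tab <- matrix(c(sig_in, sig_total - sig_in,
                  bg_in - sig_in, (bg_total - sig_total) - (bg_in - sig_in)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("sig", "nonsig"), c("in", "out")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(odds_ratio = NA_real_, p.value = 1, table = tab,
                degenerate = TRUE))
  }
  ft <- fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p.value = ft$p.value, table = tab,
       degenerate = FALSE)
}
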