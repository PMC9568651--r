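#' Correlate array methylation with an orthogonal per-site assay
#'
#' Pearson correlation (with two-sided t-based p) between array beta
#' values and an orthogonal per-site measurement such as the fractional
#' abundance from methylation-specific droplet digital PCR, pooled over
#' all observations and per target probe. Fractional abundance is the
#' methylated droplet count divided by total informative droplets; when
#' raw counts are supplied the fraction is computed (duplicate wells
#' summed).
#'
#' @param array_beta data.frame with subject_id, target, beta.
#' @param ortho data.frame with subject_id, target, and either
#'   `fractional_abundance` or counts `positive_methylated` /
#'   `positive_unmethylated`.
#' @return list with `pooled` (r, p.value, n) and `per_target`
#'   (data.frame target, r, p.value, n; r is NA for constant vectors).
#' @export
correlate_methods <- function(array_beta, ortho) {
  if (!"fractional_abundance" %in% names(ortho)) {
    agg <- stats::aggregate(
      cbind(positive_methylated, positive_unmethylated) ~ subject_id + target,
      data = ortho, FUN = sum)
    agg$fractional_abundance <- agg$positive_methylated /
      (agg$positive_methylated + agg$positive_unmethylated)
    ortho <- agg
  }
  m <- merge(array_beta, ortho[, c("subject_id", "target",
                                   "fractional_abundance")],
             by = c("subject_id", "target"))
  if (nrow(m) < 3L) stop("need at least 3 paired observations")
  cor_safe <- function(x, y) {
    n <- length(x)
    if (n < 3L || sd(x) == 0 || sd(y) == 0) {
      return(list(r = NA_real_, p = NA_real_, n = n))
    }
    ct <- cor.test(x, y, method = "pearson")
    list(r = unname(ct$estimate), p = ct$p.value, n = n)
  }
  pooled <- cor_safe(m$beta, m$fractional_abundance)
  per <- do.call(rbind, lapply(split(m, m$target), function(g) {
    cs <- cor_safe(g$beta, g$fractional_abundance)
    data.frame(target = g$target[1L], r = cs$r, p.value = cs$p, n = cs$n)
  }))
  rownames(per) <- NULL
  list(pooled = list(r = pooled$r, p.value = pooled$p, n = pooled$n),
       per_target = per)
}

#' Direction concordance between two methods' within-pair deltas
#'
#' Counts within-pair deltas with the same strict sign in both methods
#' (zero deltas in either method are excluded) and tests the concordant
#' fraction against 0.5 with the exact two-sided binomial test. Invariant
#' to positive rescaling of either method's deltas.
#'
#' @param delta_array within-pair deltas from the array.
#' @param delta_ortho paired within-pair deltas from the orthogonal assay.
#' @return list with `k` (concordant), `n` (informative comparisons),
#'   `proportion`, and `p.value`.
#' @export
direction_concordance <- function(delta_array, delta_ortho) {
  stopifnot(length(delta_array) == length(delta_ortho))
  ok <- !is.na(delta_array) & !is.na(delta_ortho) &
    delta_array != 0 & delta_ortho != 0
  n <- sum(ok)
  k <- sum(sign(delta_array[ok]) == sign(delta_ortho[ok]))
  p <- if (n > 0L) binom_two_sided(k, n) else NA_real_
  list(k = k, n = n, proportion = if (n > 0L) k / n else NA_real_,
       p.value = p)
}
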