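# Spatial-correlation DMR detection in the comb-p style:
# (1) estimate the autocorrelation of probit-transformed p-values as a
#     function of genomic distance, (2) smooth each probe's p with its
#     neighbours by the Stouffer-Liptak-Kechris combination, (3) seed and
#     extend candidate regions, (4) score each region by Stouffer-Liptak
#     over raw member p-values and apply the regional Sidak correction.
# One-sided probit convention throughout: z = qnorm(1 - p), large z =
# small p; effect direction is carried separately by coefficient signs.

.z_from_p <- function(p) {
  qnorm(pmin(pmax(p, 1e-300), 1 - 1e-16), lower.tail = FALSE)
}

#' Estimate spatial autocorrelation of p-values
#'
#' For each distance bin (half-open, width `bin_size`, starting at 1 bp),
#' the Pearson correlation of probit-transformed p-values `z = qnorm(1-p)`
#' over all probe pairs whose genomic distance falls in the bin, pooled
#' across chromosomes. Bins with fewer than `min_pairs` pairs are set to 0
#' with a warning.
#'
#' @param positions probe positions (1-based), sorted within chromosome.
#' @param chrom chromosome per probe.
#' @param pvalues raw p-values per probe.
#' @param max_dist largest distance considered (default 750 bp).
#' @param bin_size bin width in bp (default 50).
#' @param min_pairs minimum pairs per bin (default 10).
#' @return data.frame with bin_start, bin_end (half-open), cor, n_pairs.
#' @export
estimate_acf <- function(positions, chrom, pvalues, max_dist = 750L,
                         bin_size = 50L, min_pairs = 10L) {
  z <- .z_from_p(pvalues)
  ok <- !is.na(z)
  breaks <- seq(1L, max_dist + bin_size, by = bin_size)
  breaks <- breaks[breaks <= max_dist + 1L]
  if (breaks[length(breaks)] < max_dist + 1L) {
    breaks <- c(breaks, max_dist + 1L)
  }
  nb <- length(breaks) - 1L
  zi <- vector("list", 0); zj <- vector("list", 0); dd <- vector("list", 0)
  o <- order(chrom, positions)
  pos <- positions[o]; chr <- chrom[o]; zz <- z[o]; okk <- ok[o]
  n <- length(pos)
  lag <- 1L
  repeat {
    if (lag >= n) break
    i <- seq_len(n - lag)
    j <- i + lag
    d <- pos[j] - pos[i]
    sel <- chr[i] == chr[j] & d <= max_dist & d >= 1L & okk[i] & okk[j]
    if (!any(sel)) break
    zi <- c(zi, list(zz[i[sel]])); zj <- c(zj, list(zz[j[sel]]))
    dd <- c(dd, list(d[sel]))
    lag <- lag + 1L
  }
  zi <- unlist(zi); zj <- unlist(zj); dd <- unlist(dd)
  out <- data.frame(bin_start = breaks[-length(breaks)],
                    bin_end = breaks[-1L], cor = 0, n_pairs = 0L)
  if (length(dd)) {
    bin <- findInterval(dd, breaks, rightmost.closed = FALSE)
    for (b in seq_len(nb)) {
      sel <- bin == b
      out$n_pairs[b] <- sum(sel)
      if (sum(sel) >= min_pairs) {
        r <- suppressWarnings(cor(zi[sel], zj[sel]))
        out$cor[b] <- if (is.na(r)) 0 else max(-1, min(1, r))
      }
    }
  }
  empty <- out$n_pairs < min_pairs
  if (any(empty)) {
    warning(sum(empty), " distance bin(s) with fewer than ", min_pairs,
            " pairs; correlation set to 0")
  }
  out
}

.acf_lookup <- function(acf, d) {
  # distance 0 is perfect correlation by definition
  r <- numeric(length(d))
  r[d == 0] <- 1
  idx <- findInterval(d, c(acf$bin_start, acf$bin_end[nrow(acf)]))
  inside <- d > 0 & idx >= 1L & idx <= nrow(acf)
  r[inside] <- acf$cor[idx[inside]]
  r
}

# Stouffer-Liptak combination of the z-scores of `p` with pairwise
# correlations sigma(d_jl): z_comb = sum(z) / sqrt(k + 2 sum_{j<l} sigma)
.slk_combine <- function(p, pos, acf) {
  k <- length(p)
  z <- .z_from_p(p)
  if (k == 1L) return(list(p = p, fallback = FALSE))
  cs <- 0
  for (a in seq_len(k - 1L)) {
    cs <- cs + sum(.acf_lookup(acf, abs(pos[(a + 1L):k] - pos[a])))
  }
  v <- k + 2 * cs
  fallback <- FALSE
  if (v <= 0) { v <- k; fallback <- TRUE }
  list(p = pnorm(sum(z) / sqrt(v), lower.tail = FALSE), fallback = fallback)
}

#' Stouffer-Liptak smoothing of p-values over genomic windows
#'
#' Replaces each probe's p-value with the correlation-adjusted Stouffer
#' combination of all probes within `window` bp on the same chromosome
#' (including itself). Isolated probes are returned unchanged. A
#' non-positive variance arising from a pathological autocorrelation table
#' falls back to the independence combination for that probe (logged).
#'
#' @param pvalues raw p-values.
#' @param positions probe positions (1-based).
#' @param chrom chromosome per probe.
#' @param acf autocorrelation table from [estimate_acf()].
#' @param window neighbourhood half-width in bp (default 750).
#' @return vector of corrected p-values, same order as input.
#' @export
slk_correct <- function(pvalues, positions, chrom, acf, window = 750L) {
  o <- order(chrom, positions)
  pos <- positions[o]; chr <- chrom[o]; p <- pvalues[o]
  n <- length(p)
  out <- rep(NA_real_, n)
  n_fallback <- 0L
  lo <- 1L
  hi <- 1L
  for (i in seq_len(n)) {
    if (is.na(p[i])) next
    while (lo < i && (chr[lo] != chr[i] || pos[i] - pos[lo] > window)) {
      lo <- lo + 1L
    }
    if (hi < i) hi <- i
    while (hi < n && chr[hi + 1L] == chr[i] &&
           pos[hi + 1L] - pos[i] <= window) {
      hi <- hi + 1L
    }
    idx <- lo:hi
    idx <- idx[!is.na(p[idx])]
    cmb <- .slk_combine(p[idx], pos[idx], acf)
    out[i] <- cmb$p
    if (cmb$fallback) n_fallback <- n_fallback + 1L
  }
  if (n_fallback > 0L) {
    warning("independence fallback used for ", n_fallback,
            " probe(s) with non-positive combination variance")
  }
  out[order(o)]
}

#' Seed and extend candidate regions from corrected p-values
#'
#' Regions are maximal runs of probes with corrected p below `seed_p`
#' whose successive inter-probe gaps are at most `dist` bp on one
#' chromosome; runs of fewer than 2 probes are discarded.
#'
#' @param corrected_p corrected p-values.
#' @param positions probe positions (1-based).
#' @param chrom chromosome per probe.
#' @param seed_p seeding/extension threshold (default 0.01).
#' @param dist maximum inter-probe gap in bp (default 750).
#' @return list of integer vectors indexing the input probes.
#' @export
find_regions <- function(corrected_p, positions, chrom, seed_p = 0.01,
                         dist = 750L) {
  o <- order(chrom, positions)
  hit <- !is.na(corrected_p[o]) & corrected_p[o] < seed_p
  pos <- positions[o]; chr <- chrom[o]
  regions <- list()
  current <- integer(0)
  for (i in seq_along(hit)) {
    if (hit[i]) {
      if (length(current) &&
          (chr[i] != chr[current[length(current)]] ||
           pos[i] - pos[current[length(current)]] > dist)) {
        if (length(current) >= 2L) regions[[length(regions) + 1L]] <- current
        current <- integer(0)
      }
      current <- c(current, i)
    } else {
      if (length(current) >= 2L) regions[[length(regions) + 1L]] <- current
      current <- integer(0)
    }
  }
  if (length(current) >= 2L) regions[[length(regions) + 1L]] <- current
  lapply(regions, function(idx) o[idx])
}

#' Score a candidate region
#'
#' Combined p by Stouffer-Liptak over the member probes' raw p-values
#' with autocorrelation-derived pairwise correlations; Sidak-corrected
#' p = 1 - (1 - combined p)^(total_bases / width); direction string from
#' the member coefficients in genomic order (e.g. "- - +").
#'
#' @param members integer indices of the member probes.
#' @param raw_p raw p-values (full vector).
#' @param positions,chrom probe coordinates (full vectors).
#' @param coefs regression coefficients (full vector).
#' @param probe_ids probe identifiers (full vector).
#' @param acf autocorrelation table.
#' @param total_bases total assayed bases for the Sidak exponent.
#' @return one-row data.frame: chrom, start, end (1-based inclusive),
#'   width, n_probes, probes, direction, combined_p, sidak_p.
#' @export
score_region <- function(members, raw_p, positions, chrom, coefs,
                         probe_ids, acf, total_bases) {
  stopifnot(length(members) >= 2L)
  ord <- members[order(positions[members])]
  start <- positions[ord[1L]]
  end <- positions[ord[length(ord)]]
  width <- end - start + 1L
  if (width <= 0L) stop("region has non-positive width")
  cmb <- .slk_combine(raw_p[ord], positions[ord], acf)
  pc <- cmb$p
  expo <- total_bases / width
  sidak <- -expm1(expo * log1p(-pc))
  sidak <- min(1, max(sidak, pc))   # never below the combined p
  data.frame(chrom = chrom[ord[1L]], start = start, end = end,
             width = width, n_probes = length(ord),
             probes = paste(probe_ids[ord], collapse = ";"),
             direction = paste(ifelse(coefs[ord] < 0, "-", "+"),
                               collapse = " "),
             combined_p = pc, sidak_p = sidak,
             stringsAsFactors = FALSE)
}

#' Call differentially methylated regions from EWAS results
#'
#' Full scan: autocorrelation estimation, Stouffer-Liptak smoothing,
#' region seeding/extension, and regional scoring with Sidak correction.
#' `total_bases` for the Sidak exponent is the sum over chromosomes of the
#' analyzed probe span (max - min position + 1).
#'
#' @param ewas EWAS result data.frame from [run_ewas()].
#' @param manifest probe manifest (probe_id, chrom, pos).
#' @param seed_p seeding threshold (default 0.01).
#' @param dist maximum inter-probe gap (default 750 bp).
#' @param window smoothing window (default 750 bp).
#' @param max_dist,bin_size autocorrelation controls.
#' @param sidak_alpha significance threshold on the Sidak p (default 0.05).
#' @param gc_correct apply genomic-control rescaling (divide the
#'   association chi-square by the inflation factor lambda when lambda > 1)
#'   before the scan (default FALSE). Genomic control treats all
#'   inflation as artifactual; under pervasive genuine signal (many
#'   probes carrying small true effects) it discounts real regions, so it
#'   is off unless residual technical inflation is suspected.
#' @return data.frame of candidate regions sorted by Sidak p with a
#'   `significant` flag; the autocorrelation table and parameters are
#'   attached as attributes `acf` and `params` (including the lambda used).
#' @export
call_dmrs <- function(ewas, manifest, seed_p = 0.01, dist = 750L,
                      window = 750L, max_dist = 750L, bin_size = 50L,
                      sidak_alpha = 0.05, gc_correct = FALSE) {
  m <- manifest[match(ewas$probe_id, manifest$probe_id), ]
  keep <- !is.na(ewas$p.value) & !is.na(m$pos)
  p <- ewas$p.value[keep]
  pos <- m$pos[keep]
  chr <- m$chrom[keep]
  coefs <- ewas$coef[keep]
  ids <- ewas$probe_id[keep]

  lambda_gc <- genomic_inflation(p, warn = FALSE)
  if (gc_correct && !is.na(lambda_gc) && lambda_gc > 1) {
    p <- pchisq(qchisq(p, df = 1, lower.tail = FALSE) / lambda_gc,
                df = 1, lower.tail = FALSE)
  }

  acf <- suppressWarnings(
    estimate_acf(pos, chr, p, max_dist = max_dist, bin_size = bin_size))
  pc <- slk_correct(p, pos, chr, acf, window = window)
  regions <- find_regions(pc, pos, chr, seed_p = seed_p, dist = dist)

  spans <- tapply(pos, chr, function(x) max(x) - min(x) + 1L)
  total_bases <- sum(spans)

  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), width = integer(),
                      n_probes = integer(), probes = character(),
                      direction = character(), combined_p = numeric(),
                      sidak_p = numeric(), significant = logical(),
                      stringsAsFactors = FALSE)
  out <- if (length(regions)) {
    do.call(rbind, lapply(regions, score_region, raw_p = p, positions = pos,
                          chrom = chr, coefs = coefs, probe_ids = ids,
                          acf = acf, total_bases = total_bases))
  } else empty[, setdiff(names(empty), "significant")]
  if (nrow(out)) {
    out$significant <- out$sidak_p < sidak_alpha
    out <- out[order(out$sidak_p), ]
    rownames(out) <- NULL
  } else {
    out <- empty
  }
  attr(out, "acf") <- acf
  attr(out, "params") <- list(seed_p = seed_p, dist = dist, window = window,
                              max_dist = max_dist, bin_size = bin_size,
                              sidak_alpha = sidak_alpha,
                              total_bases = total_bases,
                              gc_correct = gc_correct, lambda = lambda_gc)
  out
}
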