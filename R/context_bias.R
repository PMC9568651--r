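#' Overlap probes with an interval track
#'
#' Membership of manifest probes (1-based point coordinates) in a track of
#' 0-based half-open intervals: probe with position `pos` is a member of
#' `[start, end)` iff `start <= pos - 1 < end`. Chromosome names are
#' normalized ("1" vs "chr1") with a warning when the conventions differ.
#'
#' @param manifest manifest data.frame (probe_id, chrom, pos).
#' @param track data.frame with chrom, start, end and optionally name
#'   (class label).
#' @return data.frame: probe_id, one logical column per class label (or a
#'   single `member` column for unnamed tracks).
#' @export
overlap_probes <- function(manifest, track) {
  norm_chr <- function(x) ifelse(grepl("^chr", x), x, paste0("chr", x))
  mchr <- manifest$chrom
  tchr <- track$chrom
  if (length(tchr) && (any(grepl("^chr", mchr)) != any(grepl("^chr", tchr)))) {
    warning("normalizing chromosome naming between manifest and track")
  }
  mchr <- norm_chr(mchr)
  tchr <- norm_chr(tchr)
  probes <- GenomicRanges::GRanges(
    mchr, IRanges::IRanges(start = manifest$pos, width = 1L))
  # BED 0-based half-open [start, end) -> 1-based closed [start+1, end]
  ivs <- GenomicRanges::GRanges(
    tchr, IRanges::IRanges(start = track$start + 1L, end = track$end))
  classes <- if ("name" %in% names(track)) track$name else
    rep("member", nrow(track))
  hits <- GenomicRanges::findOverlaps(probes, ivs)
  out <- data.frame(probe_id = manifest$probe_id)
  for (cl in unique(classes)) {
    member <- rep(FALSE, nrow(manifest))
    sel <- classes[S4Vectors::subjectHits(hits)] == cl
    member[unique(S4Vectors::queryHits(hits)[sel])] <- TRUE
    out[[cl]] <- member
  }
  out$any_class <- if (length(unique(classes))) {
    rowSums(as.matrix(out[, unique(classes), drop = FALSE])) > 0
  } else rep(FALSE, nrow(manifest))
  out
}

#' Tally regression-coefficient signs
#'
#' Counts strictly negative and strictly positive coefficients among
#' probes with status `ok`; exact zeros are excluded from both tallies and
#' counted separately.
#'
#' @param coefs numeric coefficients (NA allowed).
#' @return list with n_negative, n_positive, n_zero.
#' @export
tally_signs <- function(coefs) {
  x <- coefs[!is.na(coefs)]
  list(n_negative = sum(x < 0), n_positive = sum(x > 0),
       n_zero = sum(x == 0))
}

#' Per-stratum delta-beta location test
#'
#' For a probe stratum, the per-pair medians of delta-beta over member
#' probes, their median and IQR, and a two-sided one-sample Wilcoxon
#' signed-rank test against zero.
#'
#' @param delta delta-beta matrix (probes x pairs).
#' @param member logical vector or probe ids selecting the stratum.
#' @return list with `pair_medians`, `median`, `iqr`, `p.value`, `n_pairs`.
#' @export
stratum_delta_beta <- function(delta, member) {
  rows <- if (is.logical(member)) which(member) else
    which(rownames(delta) %in% member)
  if (!length(rows)) return(NULL)
  pm <- apply(delta[rows, , drop = FALSE], 2L, median, na.rm = TRUE)
  nz <- sum(pm != 0, na.rm = TRUE)
  p <- if (all(pm == 0, na.rm = TRUE)) 1 else if (nz < 2L) NA_real_ else
    wilcoxon_signed_rank(pm)$p.value
  list(pair_medians = pm, median = median(pm, na.rm = TRUE),
       iqr = IQR(pm, na.rm = TRUE), p.value = p, n_pairs = length(pm))
}

#' BH-FDR adjustment within test families
#'
#' Applies Benjamini-Hochberg separately within each family label,
#' following the convention of correcting within an analysis (one family
#' per table or figure panel) rather than globally.
#'
#' @param p p-values.
#' @param family family label per test.
#' @return q-values, same order.
#' @export
fdr_by_family <- function(p, family) {
  stopifnot(length(p) == length(family))
  q <- rep(NA_real_, length(p))
  for (f in unique(family)) {
    idx <- which(family == f)
    q[idx] <- bh_fdr(p[idx])
  }
  q
}

.collect_strata <- function(manifest, tracks = NULL) {
  strata <- list()
  fam <- character(0)
  strata[["All probes"]] <- rep(TRUE, nrow(manifest))
  fam["All probes"] <- "cpg_context"
  for (ctx in c("OpenSea", "Island", "Shore", "Shelf")) {
    strata[[ctx]] <- manifest$island_relation == ctx
    fam[ctx] <- "cpg_context"
  }
  strata[["Shelf/shore"]] <- manifest$island_relation %in% c("Shelf", "Shore")
  fam["Shelf/shore"] <- "cpg_context"
  groups <- unique(unlist(strsplit(manifest$refgene_groups[
    nzchar(manifest$refgene_groups)], ";", fixed = TRUE)))
  for (g in sort(groups)) {
    strata[[g]] <- vapply(strsplit(manifest$refgene_groups, ";", fixed = TRUE),
                          function(x) g %in% x, logical(1))
    fam[g] <- "refgene"
  }
  for (rf in sort(unique(manifest$reg_feature))) {
    nm <- paste0("RegFeature:", rf)
    strata[[nm]] <- manifest$reg_feature == rf
    fam[nm] <- "reg_feature"
  }
  if (!is.null(tracks)) {
    for (tn in names(tracks)) {
      ov <- overlap_probes(manifest, tracks[[tn]])
      cls <- setdiff(names(ov), c("probe_id", "any_class"))
      for (cl in cls) {
        nm <- paste0(tn, ":", cl)
        strata[[nm]] <- ov[[cl]][match(manifest$probe_id, ov$probe_id)]
        fam[nm] <- tn
      }
    }
  }
  list(strata = strata, family = fam)
}

#' Genomic-context hypomethylation bias suite
#'
#' For each stratum (full array, island-relation contexts including the
#' collapsed shelf/shore, RefGene groups, regulatory-feature groups, and
#' any supplied annotation track classes): the negative/positive
#' coefficient tally with an exact two-sided binomial test against 0.5,
#' and the per-pair median delta-beta with a Wilcoxon signed-rank test
#' against zero. FDR is computed within family, separately for the sign
#' tests and the delta-beta tests.
#'
#' @param ewas EWAS result data.frame (uses rows with status "ok").
#' @param delta delta-beta matrix (probes x pairs).
#' @param manifest probe manifest.
#' @param tracks optional named list of interval-track data.frames.
#' @return data.frame with one row per stratum: stratum, family,
#'   n_negative, n_positive, n_zero, pct_negative, binom_p, binom_fdr,
#'   median_delta_beta, iqr_delta_beta, wilcox_p, wilcox_fdr, n_probes.
#' @export
run_bias_suite <- function(ewas, delta, manifest, tracks = NULL) {
  ewas <- ewas[match(manifest$probe_id, ewas$probe_id), ]
  ok <- !is.na(ewas$p.value) & ewas$status == "ok"
  coefs <- ifelse(ok, ewas$coef, NA_real_)
  st <- .collect_strata(manifest, tracks)
  rows <- list()
  for (nm in names(st$strata)) {
    member <- st$strata[[nm]] & !is.na(st$strata[[nm]])
    n_probes <- sum(member)
    if (n_probes == 0L) next  # empty stratum: row omitted
    tally <- tally_signs(coefs[member])
    n_tested <- tally$n_negative + tally$n_positive
    bp <- if (n_tested > 0L) {
      binom_two_sided(tally$n_negative, n_tested)
    } else NA_real_
    db <- stratum_delta_beta(delta, manifest$probe_id[member])
    rows[[nm]] <- data.frame(
      stratum = nm, family = unname(st$family[nm]),
      n_probes = n_probes,
      n_negative = tally$n_negative, n_positive = tally$n_positive,
      n_zero = tally$n_zero,
      pct_negative = if (n_tested > 0L) 100 * tally$n_negative / n_tested
                     else NA_real_,
      binom_p = bp,
      median_delta_beta = db$median, iqr_delta_beta = db$iqr,
      wilcox_p = db$p.value, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$binom_fdr <- fdr_by_family(out$binom_p, out$family)
  out$wilcox_fdr <- fdr_by_family(out$wilcox_p, out$family)
  out
}
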