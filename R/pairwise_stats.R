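#' Within-pair delta-beta matrix
#'
#' One column per twin pair, value = case beta minus control beta; missing
#' if either member is missing.
#'
#' @param beta beta matrix (probes x subjects).
#' @param sheet sample sheet defining the pairing.
#' @return probes x pairs matrix of delta-beta values.
#' @export
delta_beta <- function(beta, sheet) {
  validate_sample_sheet(sheet)
  missing_subj <- setdiff(sheet$subject_id, colnames(beta))
  if (length(missing_subj)) {
    stop("pair member(s) absent from beta matrix: ",
         paste(head(missing_subj, 5L), collapse = ", "))
  }
  pairs <- unique(sheet$pair_id)
  cases <- sheet$subject_id[sheet$role == "case"][
    match(pairs, sheet$pair_id[sheet$role == "case"])]
  ctrls <- sheet$subject_id[sheet$role == "control"][
    match(pairs, sheet$pair_id[sheet$role == "control"])]
  d <- beta[, cases, drop = FALSE] - beta[, ctrls, drop = FALSE]
  colnames(d) <- pairs
  d
}

#' Recurrently variable probes by absolute delta-beta threshold
#'
#' Counts, per probe, the pairs whose absolute delta-beta meets the
#' threshold (inclusive, `|delta| >= threshold`); probes meeting it in at
#' least `min_pairs` pairs form the recurrent set. The count under the
#' strict rule (`>`) is reported alongside for auditability, and probes
#' are aggregated to genes when the manifest is supplied (a probe
#' annotated to several genes counts once per gene).
#'
#' @param delta delta-beta matrix from [delta_beta()].
#' @param threshold absolute delta-beta cutoff (default 0.15).
#' @param min_pairs minimum number of exceeding pairs (default 2).
#' @param manifest optional manifest with a `gene` column for gene-level
#'   aggregation of the recurrent set.
#' @return list with `report` (per-probe counts and recurrent flag),
#'   `recurrent_probes`, `n_exceeding_probes` (>= threshold in >= 1 pair),
#'   `pair_exceedances` (per pair, the probes meeting the threshold), and
#'   `recurrent_genes` (when manifest given).
#' @export
recurrent_variable_probes <- function(delta, threshold = 0.15,
                                      min_pairs = 2L, manifest = NULL) {
  hit <- abs(delta) >= threshold
  count <- rowSums(hit, na.rm = TRUE)
  count_strict <- rowSums(abs(delta) > threshold, na.rm = TRUE)
  report <- data.frame(probe_id = rownames(delta),
                       n_pairs_exceeding = count,
                       n_pairs_exceeding_strict = count_strict,
                       recurrent = count >= min_pairs,
                       row.names = NULL)
  out <- list(report = report,
              recurrent_probes = report$probe_id[report$recurrent],
              n_exceeding_probes = sum(count >= 1L),
              pair_exceedances = apply(hit, 2L, function(h)
                rownames(delta)[which(h)], simplify = FALSE))
  if (!is.null(manifest) && "gene" %in% names(manifest)) {
    genes <- manifest$gene[match(out$recurrent_probes, manifest$probe_id)]
    genes <- unlist(strsplit(genes[!is.na(genes)], ";", fixed = TRUE))
    out$recurrent_genes <- sort(unique(genes))
  }
  out
}

#' Per-pair correlation between case and control beta values
#'
#' Rank (Spearman, default) or Pearson correlation between the case and
#' control beta vectors of each pair; a QC statistic for monozygotic twin
#' cohorts, where correlations are expected above ~0.95.
#'
#' @param beta beta matrix.
#' @param sheet sample sheet.
#' @param method "spearman" (default) or "pearson".
#' @return data.frame with pair_id and correlation (NA, with a warning,
#'   for constant vectors).
#' @export
pair_correlation <- function(beta, sheet, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  validate_sample_sheet(sheet)
  if (nrow(beta) < 3L) stop("need at least 3 shared probes")
  pairs <- unique(sheet$pair_id)
  r <- rep(NA_real_, length(pairs))
  for (i in seq_along(pairs)) {
    rows <- sheet[sheet$pair_id == pairs[i], ]
    x <- beta[, rows$subject_id[rows$role == "case"]]
    y <- beta[, rows$subject_id[rows$role == "control"]]
    ok <- !is.na(x) & !is.na(y)
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      warning("constant beta vector in pair ", pairs[i],
              "; correlation set to NA")
      next
    }
    r[i] <- cor(x[ok], y[ok], method = method)
  }
  data.frame(pair_id = pairs, correlation = r)
}

#' Global methylation content and its paired comparison
#'
#' Summarizes each subject's global DNA-methylation content as the median
#' (or mean) beta over all probes and compares cases with controls across
#' pairs by a two-sided paired Wilcoxon signed-rank test.
#'
#' @param beta beta matrix.
#' @param sheet sample sheet.
#' @param statistic "median" (default) or "mean".
#' @return list with `per_subject` (data.frame subject_id, content),
#'   `p.value`, and `n_pairs`.
#' @export
global_content <- function(beta, sheet, statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  validate_sample_sheet(sheet)
  fun <- if (statistic == "median") median else mean
  content <- apply(beta[, sheet$subject_id, drop = FALSE], 2L, fun,
                   na.rm = TRUE)
  pairs <- unique(sheet$pair_id)
  case_c <- content[sheet$subject_id[sheet$role == "case"][
    match(pairs, sheet$pair_id[sheet$role == "case"])]]
  ctrl_c <- content[sheet$subject_id[sheet$role == "control"][
    match(pairs, sheet$pair_id[sheet$role == "control"])]]
  d <- case_c - ctrl_c
  p <- if (all(d == 0)) 1 else wilcoxon_signed_rank(d)$p.value
  list(per_subject = data.frame(subject_id = sheet$subject_id,
                                content = unname(content[sheet$subject_id])),
       case_minus_control = unname(d),
       p.value = p, n_pairs = length(pairs))
}
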