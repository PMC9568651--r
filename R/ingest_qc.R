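#' Read pipeline inputs from standard files
#'
#' Reads a beta-value matrix (TSV, first column probe ids, remaining
#' columns subject ids), a sample sheet (CSV), a probe manifest (CSV), and
#' optionally a detection-p matrix (TSV, same layout as the beta matrix).
#' Subjects are restricted to the intersection of the sample sheet and the
#' beta matrix (dropped subjects are reported with a warning), structures
#' are axis-aligned, and the pairing contract (one case + one control per
#' pair, matching sex) is enforced. Readers accept gzipped files and CRLF
#' line endings.
#'
#' @param beta_path path to the beta TSV.
#' @param sheet_path path to the sample-sheet CSV.
#' @param manifest_path path to the manifest CSV.
#' @param detp_path optional path to the detection-p TSV.
#' @return list with `beta` (matrix), `sheet` (data.frame), `manifest`
#'   (data.frame), and `detp` (matrix or NULL).
#' @export
read_inputs <- function(beta_path, sheet_path, manifest_path,
                        detp_path = NULL) {
  for (p in c(beta_path, sheet_path, manifest_path, detp_path)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  beta <- read_matrix_tsv(beta_path)
  sheet <- as.data.frame(data.table::fread(sheet_path))
  manifest <- as.data.frame(data.table::fread(manifest_path))
  detp <- if (!is.null(detp_path)) read_matrix_tsv(detp_path) else NULL

  validate_sample_sheet(sheet)
  if (anyDuplicated(manifest$probe_id)) stop("duplicate probe ids in manifest")

  common <- intersect(sheet$subject_id, colnames(beta))
  dropped <- setdiff(union(sheet$subject_id, colnames(beta)), common)
  if (length(dropped)) {
    warning("dropping ", length(dropped),
            " subject(s) absent from sheet or matrix: ",
            paste(head(dropped, 5L), collapse = ", "))
  }
  sheet <- sheet[sheet$subject_id %in% common, , drop = FALSE]
  beta <- beta[, sheet$subject_id, drop = FALSE]
  if (!is.null(detp)) detp <- detp[rownames(beta), sheet$subject_id,
                                   drop = FALSE]
  validate_sample_sheet(sheet)  # pairs must survive the intersection intact
  list(beta = beta, sheet = sheet, manifest = manifest, detp = detp)
}

read_matrix_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  ids <- dt[[1L]]
  if (anyDuplicated(ids)) stop("duplicate probe ids in ", path)
  m <- as.matrix(dt[, -1L])
  if (anyDuplicated(colnames(m))) stop("duplicate subject ids in ", path)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Validate a sample sheet's pairing structure
#'
#' Checks unique subject ids and, for every pair id, exactly one case and
#' one control of matching sex.
#'
#' @param sheet sample-sheet data.frame with columns subject_id, pair_id,
#'   role, sex.
#' @return invisibly the sheet; errors name the offending pair.
#' @export
validate_sample_sheet <- function(sheet) {
  need <- c("subject_id", "pair_id", "role", "sex")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) stop("sample sheet missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$subject_id)) stop("duplicate subject ids in sheet")
  if (!all(sheet$role %in% c("case", "control"))) {
    stop("role must be 'case' or 'control'")
  }
  for (pid in unique(sheet$pair_id)) {
    rows <- sheet[sheet$pair_id == pid, ]
    if (sum(rows$role == "case") != 1L || sum(rows$role == "control") != 1L) {
      stop("pair ", pid, " does not have exactly one case and one control")
    }
    if (length(unique(rows$sex)) != 1L) {
      stop("pair ", pid, " has mismatched sex between members")
    }
  }
  invisible(sheet)
}

#' Mask entries failing the detection-p threshold
#'
#' Entries with detection p strictly greater than `threshold` are set
#' missing; all others are unchanged.
#'
#' @param beta beta matrix.
#' @param detp detection-p matrix, same shape and dimnames.
#' @param threshold masking threshold (default 0.05, strict `>`).
#' @return beta matrix with failing entries set to NA.
#' @export
apply_detection_mask <- function(beta, detp, threshold = 0.05) {
  if (!identical(dim(beta), dim(detp))) {
    stop("beta and detection-p matrices have different shapes")
  }
  beta[detp > threshold] <- NA_real_
  beta
}

#' Remove probes and subjects exceeding a missingness cap
#'
#' Probes with a missing fraction strictly greater than `max_frac` are
#' removed first; subject missingness is then recomputed on the retained
#' probes and subjects are removed by the same strict rule. The
#' probes-then-subjects order is fixed and reported.
#'
#' @param beta beta matrix (NAs mark missing entries).
#' @param max_frac maximum tolerated missing fraction (default 0.05).
#' @return list with `beta`, `removed_probes`, `removed_subjects`.
#' @export
filter_missingness <- function(beta, max_frac = 0.05) {
  probe_frac <- rowMeans(is.na(beta))
  bad_p <- probe_frac > max_frac
  kept <- beta[!bad_p, , drop = FALSE]
  subj_frac <- colMeans(is.na(kept))
  bad_s <- subj_frac > max_frac
  kept <- kept[, !bad_s, drop = FALSE]
  if (nrow(kept) == 0L || ncol(kept) == 0L) {
    stop("missingness filter removed all probes or all subjects")
  }
  list(beta = kept,
       removed_probes = rownames(beta)[bad_p],
       removed_subjects = colnames(beta)[bad_s])
}

#' Impute missing beta values by k-nearest-neighbour probes
#'
#' For each probe with missing entries, the k nearest probes (Euclidean
#' distance over commonly observed subjects, scaled to the number of
#' shared subjects) that observe the target subject are averaged. Probes
#' with no usable neighbour fall back to the probe's row mean (logged via
#' warning). Results are clipped to \[0, 1\].
#'
#' @param beta beta matrix with missing entries.
#' @param k number of neighbour probes (default 10).
#' @return complete beta matrix.
#' @export
impute_knn <- function(beta, k = 10L) {
  miss <- which(is.na(beta), arr.ind = TRUE)
  if (nrow(miss) == 0L) return(beta)
  out <- beta
  fallback <- character(0)
  for (pi in unique(miss[, 1L])) {
    target <- beta[pi, ]
    obs <- !is.na(target)
    # pairwise-complete Euclidean distance to every other probe, rescaled
    # by the number of shared subjects so sparsity does not shrink distance
    dif <- sweep(beta[, obs, drop = FALSE], 2L, target[obs], "-")
    shared <- rowSums(!is.na(dif))
    d2 <- rowMeans(dif^2, na.rm = TRUE)
    d2[pi] <- Inf
    d2[shared == 0L] <- Inf
    for (sj in miss[miss[, 1L] == pi, 2L, drop = TRUE]) {
      has_val <- !is.na(beta[, sj])
      cand <- which(is.finite(d2) & has_val)
      if (!length(cand)) {
        out[pi, sj] <- mean(target, na.rm = TRUE)
        fallback <- c(fallback, rownames(beta)[pi])
        next
      }
      nb <- cand[order(d2[cand])][seq_len(min(k, length(cand)))]
      out[pi, sj] <- mean(beta[nb, sj])
    }
  }
  if (length(fallback)) {
    warning("row-mean fallback used for probe(s) with no complete ",
            "neighbour: ", paste(unique(fallback), collapse = ", "))
  }
  pmin(pmax(out, 0), 1)
}

#' Beta to M-value transform
#'
#' `M = log2(beta / (1 - beta))` after clipping beta to
#' `[eps, 1 - eps]`. Missing values propagate.
#'
#' @param beta beta matrix or vector in \[0, 1\].
#' @param eps boundary clip (default 1e-6).
#' @return M-values, same shape.
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' M-value to beta transform (inverse of [beta_to_m()])
#'
#' @param m M-value matrix or vector.
#' @return beta values in (0, 1), same shape.
#' @export
m_to_beta <- function(m) {
  1 / (1 + 2^(-m))
}

#' Flag twin pairs with elevated mean detection p-values
#'
#' A pair is flagged when either member's mean detection p exceeds the
#' absolute threshold or the cohort median plus `n_mad` scaled MADs.
#' Flagged pairs get `qc_fail = TRUE` in the returned sheet; downstream
#' analysis sets should exclude them.
#'
#' @param sheet sample sheet.
#' @param detp detection-p matrix (columns = subjects); when NULL the
#'   sheet is returned unchanged with a warning.
#' @param abs_threshold absolute mean-detection-p cutoff (default 0.01).
#' @param n_mad number of MADs above the median (default 3).
#' @return sheet with added columns `mean_detection_p` and `qc_fail`.
#' @export
flag_failed_pairs <- function(sheet, detp, abs_threshold = 0.01, n_mad = 3) {
  if (is.null(detp)) {
    warning("no detection-p matrix supplied; no pairs flagged")
    sheet$qc_fail <- FALSE
    return(sheet)
  }
  mdp <- colMeans(detp[, sheet$subject_id, drop = FALSE], na.rm = TRUE)
  cut2 <- median(mdp) + n_mad * mad(mdp)
  fail_subj <- mdp > abs_threshold | mdp > cut2
  fail_pairs <- unique(sheet$pair_id[fail_subj])
  sheet$mean_detection_p <- unname(mdp)
  sheet$qc_fail <- sheet$pair_id %in% fail_pairs
  sheet
}

#' @importFrom stats mad ave
NULL
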