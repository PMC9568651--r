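#' Reference-based cell-type deconvolution by constrained projection
#'
#' Estimates cell-type proportions per subject by projecting each
#' subject's beta values at deconvolution-informative probes onto purified
#' cell-type reference profiles: per subject, `p` minimizes
#' `||y - R p||^2` subject to `p >= 0` and `sum(p) <= 1`. The
#' non-negative least-squares step uses the Lawson-Hanson active-set
#' algorithm; when the unconstrained-sum solution exceeds 1 the sum
#' constraint is activated as an equality through a heavily weighted
#' augmentation row. The unexplained fraction `1 - sum(p)` and the
#' residual norm are diagnostic and no rescaling is applied.
#'
#' @param beta beta matrix (probes x subjects).
#' @param ref reference matrix (informative probes x cell types), betas in
#'   \[0, 1\], no missing values.
#' @return list with `proportions` (subjects x cell types matrix) and
#'   `residual` (per-subject residual norm).
#' @export
estimate_proportions <- function(beta, ref) {
  ref <- as.matrix(ref)
  if (ncol(ref) < 2L) stop("reference must contain at least 2 cell types")
  if (anyNA(ref)) stop("reference matrix must not contain missing values")
  shared <- intersect(rownames(beta), rownames(ref))
  if (length(shared) < ncol(ref)) {
    stop("need at least ", ncol(ref),
         " informative probes shared between beta matrix and reference (",
         length(shared), " found)")
  }
  R <- ref[shared, , drop = FALSE]
  qrR <- qr(R)
  if (qrR$rank < ncol(R)) {
    indep <- colnames(R)[qrR$pivot[seq_len(qrR$rank)]]
    stop("reference matrix is rank deficient; collinear cell types: ",
         paste(setdiff(colnames(R), indep), collapse = ", "))
  }
  Y <- beta[shared, , drop = FALSE]
  nsub <- ncol(Y)
  P <- matrix(0, nrow = nsub, ncol = ncol(R),
              dimnames = list(colnames(Y), colnames(R)))
  resid <- numeric(nsub)
  lambda <- 1e5  # weight activating the sum-to-one equality
  Raug <- rbind(R, lambda)
  for (s in seq_len(nsub)) {
    y <- Y[, s]
    if (anyNA(y)) stop("beta values at informative probes must be complete")
    p <- pracma::lsqnonneg(R, y)$x
    if (sum(p) > 1 + 1e-8) {
      p <- pracma::lsqnonneg(Raug, c(y, lambda))$x
      if (sum(p) > 1) p <- p / sum(p)  # remove penalty slack of order 1/lambda^2
    }
    P[s, ] <- p
    resid[s] <- sqrt(sum((y - R %*% p)^2))
  }
  list(proportions = P, residual = setNames(resid, colnames(Y)))
}

#' Paired comparison of cell proportions between cases and controls
#'
#' For each cell type, computes within-pair differences (case minus
#' control) and a two-sided Wilcoxon signed-rank p-value (exact for up to
#' 25 nonzero pairs without ties, normal approximation with continuity
#' correction otherwise), with BH-FDR across cell types. Cell types with
#' fewer than 2 nonzero pair differences get a missing p.
#'
#' @param props proportions matrix from [estimate_proportions()]
#'   (subjects x cell types) or the full list it returns.
#' @param sheet sample sheet defining the pairing.
#' @return data.frame with one row per cell type: mean difference, median
#'   difference, Wilcoxon p, and FDR q.
#' @export
compare_proportions_paired <- function(props, sheet) {
  if (is.list(props) && !is.matrix(props)) props <- props$proportions
  validate_sample_sheet(sheet)
  cases <- sheet$subject_id[sheet$role == "case"]
  ctrls <- sheet$subject_id[sheet$role == "control"]
  ord <- match(sheet$pair_id[sheet$role == "case"],
               sheet$pair_id[sheet$role == "control"])
  ctrls <- ctrls[ord]
  D <- props[cases, , drop = FALSE] - props[ctrls, , drop = FALSE]
  res <- data.frame(cell_type = colnames(props),
                    mean_diff = colMeans(D),
                    median_diff = apply(D, 2L, median),
                    p.value = NA_real_, row.names = NULL)
  for (j in seq_len(ncol(D))) {
    d <- D[, j]
    nz <- sum(d != 0, na.rm = TRUE)
    if (nz == 0L) {
      res$p.value[j] <- 1  # no within-pair differences at all
    } else if (nz >= 2L) {
      res$p.value[j] <- wilcoxon_signed_rank(d)$p.value
    }
  }
  res$fdr <- bh_fdr(res$p.value)
  res
}
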