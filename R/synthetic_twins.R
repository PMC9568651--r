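#' @section Synthetic twin cohorts:
#' The generator produces probes-by-subjects beta matrices for matched
#' case/control monozygotic twin pairs under a logit-normal model:
#' `logit(beta) = baseline + pair effect + plate effect + case * delta +
#' cell-mixture term + individual noise`, clipped to +/- 12 before the
#' inverse-logit so betas stay strictly inside (0, 1). Ground truth (per-
#' probe case effects, planted DMRs, true cell proportions, plate
#' assignments) is returned alongside the data.
#' @name twinewas-package
NULL

CELL_TYPES <- c("B", "CD4T", "CD8T", "Mono", "Gran", "NK", "nRBC")
ISLAND_CONTEXTS <- c("OpenSea", "Island", "Shore", "Shelf")

#' Simulation configuration for synthetic twin cohorts
#'
#' Builds and validates the configuration controlling the synthetic
#' twin-cohort generator. Defaults are calibrated so that within-pair
#' Spearman correlations of beta values fall in the high-0.97 to high-0.98
#' range typical of neonatal monozygotic twin methylomes, and case
#' hypomethylation is planted with context-specific magnitude (negative
#' mean shift in open-sea/shelf/shore probes, zero mean in islands) of
#' order 1e-3 on the beta scale.
#'
#' @param n_pairs number of twin pairs (one case + one control each).
#' @param n_probes number of array probes.
#' @param context_probs named probabilities over island-relation contexts
#'   (OpenSea, Island, Shore, Shelf); must sum to 1.
#' @param baseline_logit_means named list per context of `c(mean, sd)` for
#'   probe baselines on the logit scale.
#' @param pair_sd sd of the shared within-pair probe effect (logit scale).
#' @param indiv_sd sd of individual probe noise (logit scale) at
#'   mid-methylated probes. Noise is heteroscedastic: at a probe with
#'   baseline beta `b0` the sd is scaled by `min(1.3, 0.25 / (b0 (1 - b0)))`,
#'   which makes measurement noise approximately uniform on the beta scale
#'   (as on real arrays) and larger on the logit scale at extreme betas.
#' @param case_effect named list per context of `c(mean, sd)` for the
#'   per-probe case shift delta (logit scale); signs are random per probe.
#' @param plate_sd sd of the per-probe-per-plate batch effect (logit scale).
#' @param n_plates number of array plates; each pair's case and control are
#'   placed on different plates.
#' @param n_dmrs number of planted differentially methylated regions.
#' @param dmr_effect beta-scale shift shared by probes in planted regions
#'   (converted to the logit scale at each probe's baseline).
#' @param dirichlet_alpha 7-vector of Dirichlet concentrations for cell
#'   proportions (B, CD4T, CD8T, Mono, Gran, NK, nRBC).
#' @param n_cell_probes number of deconvolution-informative probes.
#' @param cell_offset_sd sd of per-cell-type logit offsets at informative
#'   probes.
#' @param cell_within_sd log-scale perturbation of the pair-level cell
#'   mixture for each twin: cell composition is largely shared within a
#'   pair (common intrauterine environment), with individual deviation of
#'   this magnitude.
#' @param seed integer seed; fully determines all generated output.
#' @return object of class `sim_config` (validated list).
#' @export
sim_config <- function(n_pairs = 40L,
                       n_probes = 20000L,
                       context_probs = c(OpenSea = 0.55, Island = 0.20,
                                         Shore = 0.15, Shelf = 0.10),
                       baseline_logit_means = list(
                         OpenSea = c(mean = 2.2, sd = 1.0),
                         Island  = c(mean = -2.5, sd = 0.8),
                         Shore   = c(mean = 0.0, sd = 1.5),
                         Shelf   = c(mean = 1.5, sd = 1.2)),
                       pair_sd = 0.35,
                       indiv_sd = 0.085,
                       case_effect = list(
                         OpenSea = c(mean = -0.008, sd = 0.006),
                         Island  = c(mean = 0.0,    sd = 0.005),
                         Shore   = c(mean = -0.007, sd = 0.006),
                         Shelf   = c(mean = -0.007, sd = 0.006)),
                       plate_sd = 0.04,
                       n_plates = 2L,
                       n_dmrs = 5L,
                       dmr_effect = -0.02,
                       dirichlet_alpha = c(B = 6, CD4T = 12, CD8T = 12,
                                           Mono = 10, Gran = 55, NK = 3,
                                           nRBC = 2),
                       n_cell_probes = 400L,
                       cell_offset_sd = 1.5,
                       cell_within_sd = 0.07,
                       seed = 1L) {
  cfg <- list(n_pairs = as.integer(n_pairs), n_probes = as.integer(n_probes),
              context_probs = context_probs,
              baseline_logit_means = baseline_logit_means,
              pair_sd = pair_sd, indiv_sd = indiv_sd,
              case_effect = case_effect, plate_sd = plate_sd,
              n_plates = as.integer(n_plates), n_dmrs = as.integer(n_dmrs),
              dmr_effect = dmr_effect, dirichlet_alpha = dirichlet_alpha,
              n_cell_probes = as.integer(n_cell_probes),
              cell_offset_sd = cell_offset_sd,
              cell_within_sd = cell_within_sd, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' A null configuration: no case effect, no planted regions
#'
#' @param ... overrides passed on to [sim_config()].
#' @export
null_config <- function(...) {
  zero <- lapply(ISLAND_CONTEXTS, function(x) c(mean = 0, sd = 0))
  names(zero) <- ISLAND_CONTEXTS
  sim_config(case_effect = zero, n_dmrs = 0L, dmr_effect = 0, ...)
}

validate_sim_config <- function(cfg) {
  if (cfg$n_pairs < 1L) stop("configuration error: n_pairs must be >= 1")
  if (cfg$n_probes < 1L) stop("configuration error: n_probes must be >= 1")
  cp <- cfg$context_probs
  if (!setequal(names(cp), ISLAND_CONTEXTS)) {
    stop("configuration error: context_probs must name ",
         paste(ISLAND_CONTEXTS, collapse = ", "))
  }
  if (abs(sum(cp) - 1) > 1e-8) {
    stop("configuration error: context_probs must sum to 1 (got ",
         format(sum(cp)), ")")
  }
  if (any(cp < 0)) stop("configuration error: context_probs must be >= 0")
  sds <- c(cfg$pair_sd, cfg$indiv_sd, cfg$plate_sd, cfg$cell_offset_sd,
           vapply(cfg$case_effect, function(x) x[["sd"]], 0),
           vapply(cfg$baseline_logit_means, function(x) x[["sd"]], 0))
  if (any(sds < 0)) stop("configuration error: standard deviations must be >= 0")
  if (cfg$n_plates < 2L) stop("configuration error: n_plates must be >= 2")
  if (length(cfg$dirichlet_alpha) != 7L || any(cfg$dirichlet_alpha <= 0)) {
    stop("configuration error: dirichlet_alpha must be 7 positive values")
  }
  if (cfg$n_cell_probes > cfg$n_probes) {
    stop("configuration error: n_cell_probes exceeds n_probes")
  }
  invisible(cfg)
}

# fixed sub-seed offsets per component (one global stream keyed by seed)
.seed_offset <- c(manifest = 101L, cohort = 202L, dmr = 303L, tracks = 404L)

#' Generate a synthetic probe manifest
#'
#' Samples per-probe genomic coordinates and context annotations: one
#' island-relation category per probe, zero or more RefGene groups, one
#' regulatory-feature group, and a gene symbol for gene-associated probes.
#' Inter-probe gaps are drawn from a mixture of dense (CpG-cluster-like)
#' and sparse spacings so that runs of >= 3 probes within 500 bp exist for
#' DMR planting. Positions are strictly increasing within chromosome.
#'
#' @param cfg a [sim_config()].
#' @return data.frame with columns probe_id, chrom, pos, island_relation,
#'   refgene_groups (semicolon-joined, possibly empty), reg_feature, gene.
#' @export
generate_manifest <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed + .seed_offset[["manifest"]])
  n <- cfg$n_probes
  ctx <- sample(names(cfg$context_probs), n, replace = TRUE,
                prob = cfg$context_probs)

  # sticky two-state gap process: dense CpG-cluster stretches (island-like
  # spacing, 20-120 bp) embedded in sparse background (200-4000 bp)
  dense <- logical(n)
  dense[1L] <- runif(1) < 0.32
  stay <- runif(n)
  for (i in 2:n) {
    dense[i] <- if (dense[i - 1L]) stay[i] < 0.75 else stay[i] < 0.12
  }
  gap <- ifelse(dense, sample(20:120, n, replace = TRUE),
                sample(200:4000, n, replace = TRUE))
  n_chrom <- max(1L, min(6L, n %/% 50L + 1L))
  chrom <- paste0("chr", rep(seq_len(n_chrom), each = ceiling(n / n_chrom))[1:n])
  pos <- integer(n)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos[idx] <- 10000L + cumsum(gap[idx])
  }

  refgene_vocab <- c("TSS1500", "TSS200", "5UTR", "1stExon", "Body",
                     "ExonBnd", "3UTR")
  # island probes favour promoter-proximal groups; open sea favours Body
  w_island <- c(0.25, 0.25, 0.15, 0.15, 0.12, 0.03, 0.05)
  w_open <- c(0.08, 0.04, 0.08, 0.04, 0.55, 0.06, 0.15)
  refgene <- character(n)
  gene <- rep(NA_character_, n)
  n_groups <- sample(0:2, n, replace = TRUE, prob = c(0.25, 0.6, 0.15))
  for (i in seq_len(n)) {
    if (n_groups[i] == 0L) next
    w <- if (ctx[i] == "Island") w_island else w_open
    refgene[i] <- paste(sample(refgene_vocab, n_groups[i], prob = w),
                        collapse = ";")
    gene[i] <- sprintf("G%04d", (i - 1L) %/% 7L + 1L)
  }

  reg_feature <- character(n)
  for (i in seq_len(n)) {
    p <- if (ctx[i] == "Island") c(0.50, 0.15, 0.05, 0.30)
         else c(0.05, 0.20, 0.10, 0.65)
    reg_feature[i] <- sample(c("Promoter", "Gene", "NonGene", "Unclassified"),
                             1L, prob = p)
  }

  data.frame(probe_id = sprintf("cg%08d", seq_len(n)),
             chrom = chrom, pos = pos, island_relation = ctx,
             refgene_groups = refgene, reg_feature = reg_feature,
             gene = gene, stringsAsFactors = FALSE)
}

# initial truth: baselines and per-probe case effect, no DMRs yet
.init_truth <- function(cfg, manifest) {
  n <- cfg$n_probes
  base <- numeric(n)
  delta <- numeric(n)
  for (ctx in ISLAND_CONTEXTS) {
    idx <- which(manifest$island_relation == ctx)
    if (!length(idx)) next
    bm <- cfg$baseline_logit_means[[ctx]]
    ce <- cfg$case_effect[[ctx]]
    base[idx] <- rnorm(length(idx), bm[["mean"]], bm[["sd"]])
    delta[idx] <- if (ce[["sd"]] == 0 && ce[["mean"]] == 0) 0 else
      rnorm(length(idx), ce[["mean"]], ce[["sd"]])
  }
  list(baseline = base, delta = delta,
       dmrs = data.frame(chrom = character(), start = integer(),
                         end = integer(), n_probes = integer(),
                         effect = numeric(), probes = character(),
                         stringsAsFactors = FALSE))
}

#' Plant differentially methylated regions into the simulation truth
#'
#' Selects `cfg$n_dmrs` disjoint runs of at least `min_probes` probes
#' spanning at most `span` bp and adds the shared `cfg$dmr_effect` (a
#' beta-scale shift, converted to the logit scale at each member probe's
#' baseline) to the per-probe case effect. Planted regions hold 5-8
#' probes by default, the probe density of array DMRs in dense CpG
#' clusters.
#'
#' @param cfg a [sim_config()].
#' @param manifest manifest from [generate_manifest()].
#' @param truth truth list carrying `baseline` and `delta` (as produced
#'   internally by [generate_cohort()]).
#' @param span maximum genomic span of a planted region in bp.
#' @param min_probes minimum probes per planted region (default 10;
#'   never below 3).
#' @return updated truth with `dmrs` populated and `delta` adjusted.
#' @export
plant_dmrs <- function(cfg, manifest, truth, span = 800L, min_probes = 10L) {
  if (cfg$n_dmrs == 0L) return(truth)
  min_probes <- max(3L, as.integer(min_probes))
  set.seed(cfg$seed + .seed_offset[["dmr"]])
  n <- nrow(manifest)
  # gap to the previous/next probe on the same chromosome (Inf at ends)
  gap_prev <- c(Inf, diff(manifest$pos))
  gap_prev[c(TRUE, manifest$chrom[-1L] != manifest$chrom[-n])] <- Inf
  gap_next <- c(gap_prev[-1L], Inf)
  # anchors start an isolated dense cluster: >= 750 bp of empty flank on
  # each side, so the planted region is spatially self-contained
  anchors <- which(gap_prev >= 750)
  chosen <- integer(0)
  used <- rep(FALSE, n)
  for (a in sample(anchors)) {
    members <- a
    while (max(members) < n && length(members) < 12L) {
      nxt <- max(members) + 1L
      if (gap_prev[nxt] > 150 ||
          manifest$pos[nxt] - manifest$pos[a] > span) break
      members <- c(members, nxt)
    }
    if (length(members) < min_probes) next
    if (gap_next[max(members)] < 750) next
    if (any(used[members])) next
    used[members] <- TRUE
    chosen <- c(chosen, a)
    # beta-scale shift converted at each probe's baseline slope; the slope
    # floor (0.25/1.3) matches the noise-scaling cap so planted effect size is
    # uniform relative to local noise
    beta0 <- plogis(truth$baseline[members])
    slope <- pmax(beta0 * (1 - beta0), 0.1923)
    truth$delta[members] <- truth$delta[members] + cfg$dmr_effect / slope
    truth$dmrs <- rbind(truth$dmrs, data.frame(
      chrom = manifest$chrom[a],
      start = manifest$pos[min(members)],
      end = manifest$pos[max(members)],
      n_probes = length(members),
      effect = cfg$dmr_effect,
      probes = paste(manifest$probe_id[members], collapse = ";"),
      stringsAsFactors = FALSE))
    if (length(chosen) == cfg$n_dmrs) break
  }
  if (length(chosen) < cfg$n_dmrs) {
    stop("insufficient probe density: only ", length(chosen),
         " disjoint regions of >= ", min_probes, " probes within ", span,
         " bp are available (", cfg$n_dmrs, " requested)")
  }
  truth
}

.rdirichlet <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n,
              byrow = TRUE)
  x / rowSums(x)
}

#' Generate a synthetic twin cohort
#'
#' Simulates beta values for `cfg$n_pairs` case/control twin pairs under
#' the logit-normal model described in the package overview, together with
#' a sample sheet, ground truth, and a matched cell-type reference matrix
#' for the deconvolution-informative probes.
#'
#' @param cfg a [sim_config()].
#' @param manifest manifest from [generate_manifest()] (regenerated from
#'   `cfg` when omitted).
#' @return list with elements `beta` (probes x subjects matrix),
#'   `sheet` (sample sheet data.frame), `truth` (ground-truth list), and
#'   `cell_reference` (informative probes x 7 cell types beta matrix).
#' @export
generate_cohort <- function(cfg, manifest = NULL) {
  validate_sim_config(cfg)
  if (is.null(manifest)) manifest <- generate_manifest(cfg)
  stopifnot(nrow(manifest) == cfg$n_probes)

  set.seed(cfg$seed + .seed_offset[["cohort"]])
  n <- cfg$n_probes
  npair <- cfg$n_pairs
  nsub <- 2L * npair

  truth <- .init_truth(cfg, manifest)

  # deconvolution-informative probes get near-0.5 baselines and
  # per-cell-type logit offsets
  informative <- sort(sample(n, cfg$n_cell_probes))
  truth$baseline[informative] <- rnorm(cfg$n_cell_probes, 0, 0.5)
  offsets <- matrix(rnorm(cfg$n_cell_probes * 7L, 0, cfg$cell_offset_sd),
                    nrow = cfg$n_cell_probes,
                    dimnames = list(manifest$probe_id[informative],
                                    CELL_TYPES))
  cell_reference <- plogis(truth$baseline[informative] + offsets)

  truth <- plant_dmrs(cfg, manifest, truth)

  # sample sheet: case and control of each pair on different plates
  set.seed(cfg$seed + .seed_offset[["cohort"]] + 1L)
  pair_id <- sprintf("P%03d", seq_len(npair))
  sex <- sample(c("F", "M"), npair, replace = TRUE, prob = c(0.62, 0.38))
  plate_case <- integer(npair)
  plate_ctrl <- integer(npair)
  for (i in seq_len(npair)) {
    pl <- sample(cfg$n_plates, 2L)
    plate_case[i] <- pl[1L]
    plate_ctrl[i] <- pl[2L]
  }
  sheet <- data.frame(
    subject_id = c(rbind(paste0(pair_id, "_case"), paste0(pair_id, "_ctrl"))),
    pair_id = rep(pair_id, each = 2L),
    role = rep(c("case", "control"), npair),
    sex = rep(sex, each = 2L),
    plate = sprintf("plate%d", c(rbind(plate_case, plate_ctrl))),
    stringsAsFactors = FALSE)
  # chips hold 8 subjects; numbered within plate
  sheet$chip <- ave(seq_len(nsub), sheet$plate,
                    FUN = function(i) (seq_along(i) - 1L) %/% 8L + 1L)
  sheet$chip <- paste0(sheet$plate, "_chip", sheet$chip)

  # cell mixtures: pair-level Dirichlet draw, individually perturbed --
  # twins largely share cord-blood composition
  pair_gamma <- matrix(rgamma(npair * 7L, shape = cfg$dirichlet_alpha),
                       nrow = npair, byrow = TRUE)
  subj_gamma <- pair_gamma[rep(seq_len(npair), each = 2L), ] *
    exp(matrix(rnorm(nsub * 7L, 0, cfg$cell_within_sd), nrow = nsub))
  props <- subj_gamma / rowSums(subj_gamma)
  dimnames(props) <- list(sheet$subject_id, CELL_TYPES)

  # noise scale factor: uniform beta-scale noise, capped at 3x
  beta0 <- plogis(truth$baseline)
  g <- pmin(1.3, 0.25 / pmax(beta0 * (1 - beta0), 1e-4))

  plate_eff <- matrix(rnorm(n * cfg$n_plates, 0, cfg$plate_sd), nrow = n) * g
  pair_eff <- matrix(rnorm(n * npair, 0, cfg$pair_sd), nrow = n)

  logit <- matrix(0, nrow = n, ncol = nsub,
                  dimnames = list(manifest$probe_id, sheet$subject_id))
  plate_idx <- as.integer(sub("plate", "", sheet$plate))
  is_case <- sheet$role == "case"
  pair_idx <- rep(seq_len(npair), each = 2L)
  cellterm <- offsets %*% t(props)   # informative probes x subjects
  for (s in seq_len(nsub)) {
    col <- truth$baseline + pair_eff[, pair_idx[s]] + plate_eff[, plate_idx[s]] +
      rnorm(n, 0, cfg$indiv_sd) * g
    if (is_case[s]) col <- col + truth$delta
    col[informative] <- col[informative] + cellterm[, s]
    logit[, s] <- col
  }
  logit[logit > 12] <- 12
  logit[logit < -12] <- -12
  beta <- plogis(logit)

  truth$cell_props <- props
  truth$plate <- setNames(sheet$plate, sheet$subject_id)
  truth$informative_probes <- manifest$probe_id[informative]

  list(beta = beta, sheet = sheet, truth = truth,
       cell_reference = cell_reference)
}

#' Generate synthetic annotation tracks
#'
#' Random interval tracks (0-based half-open, BED convention) over the
#' manifest's coordinate space: repeat classes, CoRSIV-like regions, cCRE
#' classes, and transcription-factor motifs. Intervals are anchored on
#' probe positions so that overlaps exist, with class labels in the name
#' field.
#'
#' @param manifest manifest data.frame.
#' @param seed integer seed.
#' @return named list of data.frames (chrom, start, end, name).
#' @export
generate_tracks <- function(manifest, seed = 1L) {
  set.seed(seed + .seed_offset[["tracks"]])
  make <- function(classes, frac, width_range) {
    idx <- which(runif(nrow(manifest)) < frac)
    if (!length(idx)) {
      return(data.frame(chrom = character(), start = integer(),
                        end = integer(), name = character()))
    }
    w <- sample(width_range[1]:width_range[2], length(idx), replace = TRUE)
    off <- sample(0:200, length(idx), replace = TRUE)
    start0 <- pmax(0L, manifest$pos[idx] - 1L - off)
    df <- data.frame(chrom = manifest$chrom[idx], start = start0,
                     end = start0 + w,
                     name = sample(classes, length(idx), replace = TRUE),
                     stringsAsFactors = FALSE)
    df[order(df$chrom, df$start), ]
  }
  list(repeats = make(c("LINE", "SINE", "LTR", "DNA", "Simple_repeat"),
                      0.30, c(150, 800)),
       corsivs = make("CoRSIV", 0.01, c(200, 600)),
       ccres = make(c("PLS", "pELS", "dELS", "CTCF"), 0.08, c(150, 350)),
       tf_motifs = make(c("CTCF", "ATF3", "SIX5", "USF1", "STAT3", "JUN"),
                        0.10, c(10, 30)))
}

#' Write a synthetic cohort to a fixture directory
#'
#' Writes the standard input files consumed by [read_inputs()]: beta TSV
#' (6 decimals), sample-sheet CSV, manifest CSV, cell-reference CSV, truth
#' JSON, config YAML, and BED annotation tracks (0-based half-open).
#'
#' @param sim result of [generate_cohort()].
#' @param manifest manifest data.frame used for the simulation.
#' @param dir output directory (created if needed).
#' @param cfg the [sim_config()] used (echoed to config.yaml); optional.
#' @param tracks optional list from [generate_tracks()].
#' @return invisibly, the named vector of written paths.
#' @export
write_fixture <- function(sim, manifest, dir, cfg = NULL, tracks = NULL) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create fixture directory: ", dir)
  }
  paths <- c(beta = file.path(dir, "beta.tsv"),
             sheet = file.path(dir, "samples.csv"),
             manifest = file.path(dir, "manifest.csv"),
             reference = file.path(dir, "cell_reference.csv"),
             truth = file.path(dir, "truth.json"),
             config = file.path(dir, "config.yaml"))

  bdt <- data.table::data.table(probe_id = rownames(sim$beta))
  for (s in colnames(sim$beta)) bdt[[s]] <- sprintf("%.6f", sim$beta[, s])
  data.table::fwrite(bdt, paths[["beta"]], sep = "\t", quote = FALSE)

  data.table::fwrite(sim$sheet, paths[["sheet"]])
  data.table::fwrite(manifest, paths[["manifest"]])

  refdt <- data.table::data.table(probe_id = rownames(sim$cell_reference))
  for (ct in colnames(sim$cell_reference)) {
    refdt[[ct]] <- sim$cell_reference[, ct]
  }
  data.table::fwrite(refdt, paths[["reference"]])

  truth_json <- list(
    delta = setNames(as.list(sim$truth$delta), rownames(sim$beta)),
    dmrs = sim$truth$dmrs,
    cell_props = as.data.frame(sim$truth$cell_props),
    plate = as.list(sim$truth$plate),
    informative_probes = sim$truth$informative_probes)
  jsonlite::write_json(truth_json, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")

  if (!is.null(cfg)) {
    yaml::write_yaml(lapply(unclass(cfg), function(x)
      if (is.list(x)) lapply(x, as.list) else x), paths[["config"]])
  }
  if (!is.null(tracks)) {
    trk_dir <- file.path(dir, "tracks")
    dir.create(trk_dir, showWarnings = FALSE)
    for (nm in names(tracks)) {
      p <- file.path(trk_dir, paste0(nm, ".bed"))
      data.table::fwrite(tracks[[nm]], p, sep = "\t", col.names = FALSE,
                         quote = FALSE)
      paths[nm] <- p
    }
  }
  invisible(paths)
}
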