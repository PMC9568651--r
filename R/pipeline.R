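#' Default pipeline configuration
#'
#' All statistical thresholds surfaced with their standard defaults:
#' detection-p masking at 0.05 (strict `>` masks), missingness cap 5%,
#' recurrence threshold |delta-beta| >= 0.15 in >= 2 pairs, probe FDR
#' 0.05, regional Sidak 0.05, and the region-scan parameters (750 bp
#' window/gap, seed p 0.01, 50 bp autocorrelation bins).
#'
#' @param ... named overrides merged into the default list.
#' @return configuration list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    simulate = TRUE,
    sim = list(),
    inputs = list(),
    thresholds = list(detection_p = 0.05, missing_frac = 0.05,
                      delta_beta = 0.15, min_pairs = 2L,
                      fdr = 0.05, sidak = 0.05),
    dmr = list(seed_p = 0.01, dist = 750L, window = 750L,
               max_dist = 750L, bin_size = 50L),
    global_statistic = "median",
    out_dir = NULL)
  modifyList(cfg, list(...))
}

read_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(default_config(), config)
  if (!is.numeric(cfg$seed)) stop("config field 'seed' must be an integer")
  cfg
}

#' Simulate a ready-to-run synthetic fixture directory
#'
#' Wraps the synthetic-cohort generator: builds the configured cohort,
#' annotation tracks, and writes all input files plus ground truth.
#'
#' @param config configuration list or YAML path (uses the `sim` and
#'   `seed` fields).
#' @param dir output directory.
#' @return invisibly, the named vector of written paths.
#' @export
simulate_fixture <- function(config, dir) {
  cfg <- read_config(config)
  sim_args <- modifyList(list(seed = cfg$seed), cfg$sim)
  scfg <- do.call(sim_config, sim_args)
  manifest <- generate_manifest(scfg)
  sim <- generate_cohort(scfg, manifest)
  tracks <- generate_tracks(manifest, seed = scfg$seed)
  write_fixture(sim, manifest, dir, cfg = scfg, tracks = tracks)
}

#' Run the full twin-EWAS pipeline
#'
#' Executes ingest and QC, cell-type deconvolution, within-pair
#' statistics, per-probe conditional logistic regression, region
#' detection, and the genomic-context bias suite, either on a simulated
#' cohort (`simulate: true`) or on files named under `inputs` (beta,
#' sheet, manifest, optional detp, reference, tracks). Deterministic
#' given the config seed. A machine-readable run report logs every filter
#' with counts in and out.
#'
#' @param config configuration list or YAML path (see [default_config()]).
#' @return list with `report`, `ewas`, `dmrs`, `bias`, `delta`,
#'   `pair_cor`, `global`, `proportions`, `sheet`, `manifest`, and (for
#'   simulated runs) `truth`.
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- read_config(config)
  th <- cfg$thresholds
  filters <- list()
  truth <- NULL
  tracks <- NULL

  checksums <- NULL
  if (isTRUE(cfg$simulate)) {
    sim_args <- modifyList(list(seed = cfg$seed), cfg$sim)
    scfg <- do.call(sim_config, sim_args)
    manifest <- generate_manifest(scfg)
    sim <- generate_cohort(scfg, manifest)
    beta <- sim$beta; sheet <- sim$sheet
    reference <- sim$cell_reference
    truth <- sim$truth
    detp <- NULL
    tracks <- generate_tracks(manifest, seed = scfg$seed)
  } else {
    inp <- cfg$inputs
    for (f in c("beta", "sheet", "manifest")) {
      if (is.null(inp[[f]])) stop("config missing required input path: ", f)
    }
    io <- read_inputs(inp$beta, inp$sheet, inp$manifest, inp$detp)
    beta <- io$beta; sheet <- io$sheet; manifest <- io$manifest
    detp <- io$detp
    in_files <- unlist(inp[c("beta", "sheet", "manifest", "detp",
                             "reference")], use.names = TRUE)
    checksums <- as.list(tools::md5sum(in_files[!is.na(in_files)]))
    reference <- if (!is.null(inp$reference)) {
      ref <- as.data.frame(data.table::fread(inp$reference))
      m <- as.matrix(ref[, -1L]); rownames(m) <- ref[[1L]]; m
    } else NULL
    if (!is.null(inp$tracks)) {
      tracks <- lapply(inp$tracks, function(p) {
        dt <- data.table::fread(p, header = FALSE)
        names(dt)[1:4] <- c("chrom", "start", "end", "name")[seq_len(
          min(4L, ncol(dt)))]
        as.data.frame(dt)
      })
    }
  }

  n0 <- dim(beta)
  if (!is.null(detp)) {
    sheet <- flag_failed_pairs(sheet, detp)
    failed <- unique(sheet$pair_id[sheet$qc_fail])
    filters$failed_pairs <- list(rule = "mean detection p", removed = failed)
    sheet <- sheet[!sheet$qc_fail, , drop = FALSE]
    beta <- beta[, sheet$subject_id, drop = FALSE]
    beta <- apply_detection_mask(beta, detp[, sheet$subject_id, drop = FALSE],
                                 th$detection_p)
    filters$detection_mask <- list(rule = paste0("detp > ", th$detection_p),
                                   n_masked = sum(is.na(beta)))
  }
  fm <- filter_missingness(beta, th$missing_frac)
  filters$missingness <- list(rule = paste0("missing fraction > ",
                                            th$missing_frac),
                              order = "probes_then_subjects",
                              probes_removed = length(fm$removed_probes),
                              subjects_removed = length(fm$removed_subjects))
  beta <- impute_knn(fm$beta)
  sheet <- sheet[sheet$subject_id %in% colnames(beta), , drop = FALSE]
  validate_sample_sheet(sheet)

  props <- NULL
  prop_tests <- NULL
  if (!is.null(reference)) {
    dec <- estimate_proportions(beta, reference)
    props <- dec$proportions
    prop_tests <- compare_proportions_paired(props, sheet)
  }

  delta <- delta_beta(beta, sheet)
  recur <- recurrent_variable_probes(delta, th$delta_beta, th$min_pairs,
                                     manifest)
  pair_cor <- pair_correlation(beta, sheet)
  glob <- global_content(beta, sheet, statistic = cfg$global_statistic)

  mvals <- beta_to_m(beta)
  ewas <- run_ewas(mvals, beta, sheet, props)

  dmrs <- call_dmrs(ewas, manifest,
                    seed_p = cfg$dmr$seed_p, dist = cfg$dmr$dist,
                    window = cfg$dmr$window, max_dist = cfg$dmr$max_dist,
                    bin_size = cfg$dmr$bin_size, sidak_alpha = th$sidak)
  bias <- run_bias_suite(ewas, delta, manifest, tracks)

  all_row <- bias[bias$stratum == "All probes", ]
  report <- list(
    version = as.character(packageVersion("twinewas")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "out_dir")],
    input_checksums = checksums,
    counts = list(
      probes_in = n0[1L], subjects_in = n0[2L],
      probes_analyzed = nrow(beta), subjects_analyzed = ncol(beta),
      pairs_analyzed = length(unique(sheet$pair_id))),
    filters = filters,
    summary = list(
      n_dmps_fdr = sum(ewas$fdr < th$fdr, na.rm = TRUE),
      n_dmrs_sidak = sum(dmrs$sidak_p < th$sidak),
      lambda = attr(ewas, "lambda"),
      pct_negative_coef = all_row$pct_negative,
      sign_bias_p = all_row$binom_p,
      global_content_p = glob$p.value,
      n_recurrent_probes = length(recur$recurrent_probes),
      pair_correlation_range = range(pair_cor$correlation, na.rm = TRUE)))

  result <- list(report = report, ewas = ewas, dmrs = dmrs, bias = bias,
                 delta = delta, recurrent = recur, pair_cor = pair_cor,
                 global = glob, proportions = props,
                 proportion_tests = prop_tests, sheet = sheet,
                 manifest = manifest, truth = truth)

  if (!is.null(cfg$out_dir)) write_outputs(result, cfg$out_dir)
  result
}

#' Write pipeline outputs to a directory
#'
#' Fixed-name TSV/CSV/JSON outputs: EWAS results, DMR table, bias table,
#' delta-beta matrix, pair correlations, proportions, and the run report.
#'
#' @param result list from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
write_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(obj, name, sep = "\t") {
    p <- file.path(dir, name)
    data.table::fwrite(obj, p, sep = sep, quote = FALSE)
    paths <<- c(paths, p)
  }
  wr(result$ewas, "ewas_results.tsv")
  # QQ-plot data: expected vs observed -log10 p over testable probes
  pv <- sort(result$ewas$p.value[!is.na(result$ewas$p.value)])
  if (length(pv)) {
    qq <- data.frame(
      expected_neglog10 = -log10(stats::ppoints(length(pv))),
      observed_neglog10 = -log10(pv))
    wr(qq, "qq_data.tsv")
  }
  wr(result$dmrs, "dmrs.tsv")
  wr(result$bias, "bias_table.tsv")
  dd <- data.table::data.table(probe_id = rownames(result$delta))
  for (cn in colnames(result$delta)) dd[[cn]] <- result$delta[, cn]
  wr(dd, "delta_beta.tsv")
  wr(result$pair_cor, "pair_correlations.csv", sep = ",")
  wr(result$recurrent$report, "recurrence_report.csv", sep = ",")
  if (!is.null(result$proportions)) {
    pp <- data.table::data.table(subject_id = rownames(result$proportions))
    for (cn in colnames(result$proportions)) {
      pp[[cn]] <- result$proportions[, cn]
    }
    wr(pp, "cell_proportions.csv", sep = ",")
  }
  rp <- file.path(dir, "run_report.json")
  jsonlite::write_json(result$report, rp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  paths <- c(paths, rp)
  invisible(paths)
}
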