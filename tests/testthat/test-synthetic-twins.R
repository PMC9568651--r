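test_that("manifest sampling respects context probabilities and determinism", {
  cfg <- sim_config(n_probes = 1000L, n_pairs = 4L, n_dmrs = 0L,
                    n_cell_probes = 10L, seed = 1L)
  man <- generate_manifest(cfg)
  expect_equal(nrow(man), 1000L)
  expect_true(all(man$island_relation %in%
                  c("OpenSea", "Island", "Shore", "Shelf")))
  # category counts within the exact binomial 99% CI of expectation
  for (ctx in names(cfg$context_probs)) {
    ci <- qbinom(c(0.005, 0.995), 1000L, cfg$context_probs[[ctx]])
    n_ctx <- sum(man$island_relation == ctx)
    expect_true(n_ctx >= ci[1] && n_ctx <= ci[2], label = ctx)
  }
  # positions strictly increasing within chromosome
  for (ch in unique(man$chrom)) {
    expect_true(all(diff(man$pos[man$chrom == ch]) > 0))
  }
  expect_identical(man, generate_manifest(cfg))
})

test_that("invalid context probabilities are a configuration error", {
  expect_error(sim_config(context_probs = c(OpenSea = 0.5, Island = 0.2,
                                            Shore = 0.15, Shelf = 0.05)),
               "sum to 1")
  expect_error(sim_config(indiv_sd = -0.1), "standard deviations")
  expect_error(sim_config(n_cell_probes = 100, n_probes = 50), "n_cell_probes")
})

test_that("null configuration plants no case effect", {
  sim <- tiny_cohort(seed = 3, case_effect = list(
    OpenSea = c(mean = 0, sd = 0), Island = c(mean = 0, sd = 0),
    Shore = c(mean = 0, sd = 0), Shelf = c(mean = 0, sd = 0)))
  expect_true(all(sim$truth$delta == 0))
})

test_that("cohort generation is deterministic with valid structure", {
  sim1 <- tiny_cohort(seed = 7)
  sim2 <- tiny_cohort(seed = 7)
  expect_identical(sim1$beta, sim2$beta)
  expect_identical(sim1$sheet, sim2$sheet)
  sim3 <- tiny_cohort(seed = 8)
  expect_false(identical(sim1$beta, sim3$beta))

  expect_true(all(sim1$beta > 0 & sim1$beta < 1))
  sh <- sim1$sheet
  validate_sample_sheet(sh)
  for (pid in unique(sh$pair_id)) {
    rows <- sh[sh$pair_id == pid, ]
    expect_true(rows$plate[1] != rows$plate[2])  # members on separate plates
  }
})

test_that("per-pair Spearman correlations sit in the monozygotic-twin range", {
  cfg <- sim_config(seed = 5)
  man <- generate_manifest(cfg)
  sim <- generate_cohort(cfg, man)
  pc <- pair_correlation(sim$beta, sim$sheet)
  expect_true(all(pc$correlation > 0.95 & pc$correlation < 0.999))
})

test_that("DMR planting gives disjoint multi-probe regions or a clear error", {
  cfg <- tiny_config(seed = 2)
  man <- generate_manifest(cfg)
  truth0 <- twinewas:::.init_truth(cfg, man)

  unchanged <- plant_dmrs(cfg, man, truth0)  # n_dmrs = 0
  expect_identical(unchanged$delta, truth0$delta)

  cfg2 <- sim_config(n_pairs = 10L, n_probes = 5000L, n_dmrs = 5L,
                     n_cell_probes = 10L, seed = 2L)
  man2 <- generate_manifest(cfg2)
  truth2 <- plant_dmrs(cfg2, man2, twinewas:::.init_truth(cfg2, man2))
  expect_equal(nrow(truth2$dmrs), 5L)
  expect_true(all(truth2$dmrs$n_probes >= 3L))
  # disjoint: sorted regions on one chromosome never overlap
  for (ch in unique(truth2$dmrs$chrom)) {
    r <- truth2$dmrs[truth2$dmrs$chrom == ch, ]
    r <- r[order(r$start), ]
    if (nrow(r) > 1) expect_true(all(r$start[-1] > r$end[-nrow(r)]))
  }
  # affected probes carry the extra (negative) shift
  affected <- unlist(strsplit(truth2$dmrs$probes, ";"))
  idx <- match(affected, man2$probe_id)
  expect_true(all(truth2$delta[idx] <
                  twinewas:::.init_truth(cfg2, man2)$delta[idx]))

  cfg_small <- sim_config(n_pairs = 4L, n_probes = 10L, n_dmrs = 5L,
                          n_cell_probes = 2L, seed = 1L)
  man_small <- generate_manifest(cfg_small)
  expect_error(plant_dmrs(cfg_small, man_small,
                          twinewas:::.init_truth(cfg_small, man_small)),
               "insufficient probe density")
})

test_that("fixtures round-trip losslessly through the readers", {
  sim <- tiny_cohort(seed = 4)
  dir <- withr::local_tempdir()
  tracks <- generate_tracks(sim$manifest, seed = 4)
  paths <- write_fixture(sim[c("beta", "sheet", "truth", "cell_reference")],
                         sim$manifest, dir, cfg = sim$cfg, tracks = tracks)
  io <- read_inputs(paths[["beta"]], paths[["sheet"]], paths[["manifest"]])
  expect_equal(io$beta, round(sim$beta, 6), tolerance = 1e-9)
  expect_equal(io$sheet$subject_id, sim$sheet$subject_id)
  expect_equal(io$manifest$pos, sim$manifest$pos)
  # truth JSON is parseable and consistent
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(length(truth$delta), nrow(sim$beta))
  # BED tracks are 0-based half-open with positive widths
  bed <- read.table(file.path(dir, "tracks", "repeats.bed"), sep = "\t")
  expect_true(all(bed$V3 > bed$V2))
  expect_true(all(bed$V2 >= 0))
})
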