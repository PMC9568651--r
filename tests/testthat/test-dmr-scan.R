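test_that("autocorrelation estimation recovers limiting cases", {
  # duplicated z at adjacent positions: short-distance bin correlation 1
  set.seed(41)
  z <- rnorm(200)
  p <- pnorm(z, lower.tail = FALSE)
  pos <- as.integer(seq(1, by = 500, length.out = 200))
  pos2 <- as.integer(sort(c(pos, pos + 10L)))
  p2 <- rep(p, each = 2)
  acf <- suppressWarnings(
    estimate_acf(pos2, rep("chr1", 400), p2, max_dist = 750, bin_size = 50))
  expect_equal(acf$cor[1], 1, tolerance = 1e-12)

  # independent uniform p-values: every bin near zero
  set.seed(42)
  n <- 20000
  posu <- cumsum(sample(50:200, n, replace = TRUE))
  acf_u <- suppressWarnings(
    estimate_acf(posu, rep("chr1", n), runif(n), max_dist = 750))
  # bins with substantial pair counts; sparse bins carry sampling noise
  well_filled <- acf_u$n_pairs >= 1000
  expect_true(all(abs(acf_u$cor[well_filled]) < 0.05))

  # bins without pairs produce zero with a warning
  pos_sparse <- c(1L, 5000L, 10000L)
  expect_warning(acf_s <- estimate_acf(pos_sparse, rep("chr1", 3),
                                       c(0.5, 0.5, 0.5), max_dist = 750),
                 "fewer than")
  expect_true(all(acf_s$cor == 0))
})

test_that("Stouffer-Liptak smoothing reproduces quantile arithmetic", {
  acf0 <- data.frame(bin_start = 1, bin_end = 751, cor = 0, n_pairs = 100)
  # isolated probe unchanged
  out1 <- slk_correct(0.05, 1000L, "chr1", acf0)
  expect_equal(out1, 0.05)
  # two neighbours each p = 0.05, independent: z = 2 * 1.6449 / sqrt(2)
  out2 <- slk_correct(c(0.05, 0.05), c(100L, 200L), c("chr1", "chr1"), acf0)
  expect_equal(out2, rep(0.0100, 2), tolerance = 1e-3)
  # perfect correlation adds no information
  acf1 <- data.frame(bin_start = 1, bin_end = 751, cor = 1, n_pairs = 100)
  out3 <- slk_correct(c(0.05, 0.05), c(100L, 200L), c("chr1", "chr1"), acf1)
  expect_equal(out3, rep(0.05, 2), tolerance = 1e-10)
})

test_that("zero autocorrelation reduces to the classic Stouffer combination", {
  set.seed(43)
  acf0 <- data.frame(bin_start = 1, bin_end = 751, cor = 0, n_pairs = 100)
  p <- runif(12, 0.001, 0.9)
  pos <- as.integer(cumsum(sample(40:60, 12, replace = TRUE)))
  out <- slk_correct(p, pos, rep("chr1", 12), acf0, window = 1e6)
  z <- qnorm(1 - p)
  classic <- pnorm(sum(z) / sqrt(length(z)), lower.tail = FALSE)
  # every probe sees the full window -> identical combination
  expect_equal(out, rep(classic, 12), tolerance = 1e-10)
})

test_that("region seeding and extension follow the gap rule", {
  acf0 <- data.frame(bin_start = 1, bin_end = 751, cor = 0, n_pairs = 100)
  regions <- find_regions(c(0.001, 0.002, 0.5), c(100L, 200L, 300L),
                          rep("chr1", 3), seed_p = 0.01, dist = 150)
  expect_length(regions, 1L)
  expect_equal(sort(regions[[1]]), c(1L, 2L))
  # single sub-threshold probe flanked by wide gaps is discarded
  none <- find_regions(c(0.5, 0.001, 0.5), c(100L, 2000L, 4000L),
                       rep("chr1", 3), seed_p = 0.01, dist = 150)
  expect_length(none, 0L)
  # nothing below the seed threshold
  expect_length(find_regions(rep(0.5, 5), 1:5 * 100L, rep("chr1", 5)), 0L)
  # a chromosome boundary breaks a run even with small coordinate gaps
  split_chr <- find_regions(c(0.001, 0.001, 0.001, 0.001),
                            c(100L, 200L, 100L, 200L),
                            c("chr1", "chr1", "chr2", "chr2"),
                            seed_p = 0.01, dist = 750)
  expect_length(split_chr, 2L)
})

test_that("region scoring applies the Sidak closed form", {
  acf0 <- data.frame(bin_start = 1, bin_end = 751, cor = 0, n_pairs = 100)
  # choose raw p so the combined p is 0.01, then exponent 100
  z_each <- qnorm(1 - 0.01) * sqrt(2) / 2
  p_each <- pnorm(z_each, lower.tail = FALSE)
  reg <- score_region(c(1L, 2L), raw_p = c(p_each, p_each),
                      positions = c(100L, 199L), chrom = c("chr1", "chr1"),
                      coefs = c(-1, -2), probe_ids = c("a", "b"),
                      acf = acf0, total_bases = 100 * 100)
  expect_equal(reg$combined_p, 0.01, tolerance = 1e-10)
  expect_equal(reg$sidak_p, 1 - 0.99^100, tolerance = 1e-6)
  expect_equal(reg$sidak_p, 0.6340, tolerance = 1e-4)
  expect_equal(reg$direction, "- -")
  expect_equal(reg$width, 100L)
  # exponent 1 leaves the combined p unchanged
  reg1 <- score_region(c(1L, 2L), c(p_each, p_each), c(100L, 199L),
                       c("chr1", "chr1"), c(-1, 2), c("a", "b"), acf0,
                       total_bases = 100)
  expect_equal(reg1$sidak_p, reg1$combined_p, tolerance = 1e-12)
  expect_equal(reg1$direction, "- +")
  # combined p of zero stays zero
  reg0 <- score_region(c(1L, 2L), c(1e-320, 1e-320), c(100L, 199L),
                       c("chr1", "chr1"), c(-1, -1), c("a", "b"), acf0,
                       total_bases = 1e6)
  expect_equal(reg0$sidak_p, 0)
  # Sidak p is monotone in the exponent
  expos <- c(1, 10, 100, 1000)
  sp <- vapply(expos, function(e)
    score_region(c(1L, 2L), c(p_each, p_each), c(100L, 199L),
                 c("chr1", "chr1"), c(-1, -1), c("a", "b"), acf0,
                 total_bases = e * 100)$sidak_p, 0)
  expect_true(all(diff(sp) > 0))
})

test_that("DMR calls are invariant to a constant genomic shift", {
  sim <- tiny_cohort(seed = 44, n_probes = 4000L, n_dmrs = 2L,
                     n_pairs = 20L)
  mv <- beta_to_m(sim$beta)
  ewas <- run_ewas(mv, sim$beta, sim$sheet)
  d1 <- call_dmrs(ewas, sim$manifest)
  man2 <- sim$manifest
  man2$pos <- man2$pos + 5000L
  d2 <- call_dmrs(ewas, man2)
  expect_equal(d1$start + 5000L, d2$start)
  expect_equal(d1$combined_p, d2$combined_p, tolerance = 1e-12)
  expect_equal(d1$sidak_p, d2$sidak_p, tolerance = 1e-12)
})

test_that("planted regions are recovered with correct direction strings", {
  cfg <- sim_config(seed = 45, n_probes = 8000L, n_pairs = 40L,
                    n_dmrs = 3L, n_cell_probes = 100L)
  man <- generate_manifest(cfg)
  sim <- generate_cohort(cfg, man)
  mv <- beta_to_m(sim$beta)
  dec <- estimate_proportions(sim$beta, sim$cell_reference)
  ewas <- run_ewas(mv, sim$beta, sim$sheet, dec$proportions)
  dmrs <- call_dmrs(ewas, man)
  sig <- dmrs[dmrs$significant, ]
  tr <- sim$truth$dmrs
  hits <- sum(vapply(seq_len(nrow(tr)), function(i)
    any(sig$chrom == tr$chrom[i] & sig$start <= tr$end[i] &
        sig$end >= tr$start[i]), logical(1)))
  expect_gte(hits, 2L)
  # direction strings: one sign token per member probe
  expect_true(all(lengths(strsplit(sig$direction, " ")) == sig$n_probes))
  # hypomethylation plant: most member signs negative
  signs <- unlist(strsplit(sig$direction, " "))
  expect_gt(mean(signs == "-"), 0.8)
})
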