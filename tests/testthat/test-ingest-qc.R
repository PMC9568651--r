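test_that("detection-p masking uses a strict threshold", {
  beta <- toy_beta()
  detp <- matrix(0, nrow = 3, ncol = 4, dimnames = dimnames(beta))
  detp["cg1", "s1"] <- 0.06   # masked
  detp["cg2", "s2"] <- 0.05   # exactly at threshold: retained
  masked <- apply_detection_mask(beta, detp)
  expect_true(is.na(masked["cg1", "s1"]))
  expect_equal(masked["cg2", "s2"], beta["cg2", "s2"])
  expect_equal(sum(is.na(masked)), 1L)
  # all-pass matrix unchanged
  expect_equal(apply_detection_mask(beta, detp * 0), beta)
  expect_error(apply_detection_mask(beta, detp[1:2, ]), "shape")
})

test_that("missingness filter removes probes first, then subjects, strictly above 5%", {
  set.seed(2)
  beta <- matrix(runif(100 * 100), nrow = 100,
                 dimnames = list(sprintf("cg%03d", 1:100),
                                 sprintf("s%03d", 1:100)))
  beta["cg001", 1:6] <- NA  # 6% missing -> removed
  beta["cg002", 1:5] <- NA  # exactly 5% -> retained
  res <- filter_missingness(beta)
  expect_equal(res$removed_probes, "cg001")
  expect_true("cg002" %in% rownames(res$beta))
  expect_length(res$removed_subjects, 0L)

  clean <- filter_missingness(toy_beta())
  expect_equal(clean$beta, toy_beta())

  # a subject failing only before probe removal is kept (order matters)
  beta2 <- matrix(runif(40 * 20), nrow = 40,
                  dimnames = list(sprintf("p%02d", 1:40),
                                  sprintf("t%02d", 1:20)))
  beta2[1:4, "t01"] <- NA          # 10% of t01, concentrated in 4 probes
  beta2[1:4, sample(2:20, 3)] <- NA  # those probes also fail elsewhere
  beta2[1:4, ] <- NA               # all 4 probes fully missing -> removed
  res2 <- filter_missingness(beta2)
  expect_equal(res2$removed_probes, sprintf("p%02d", 1:4))
  expect_length(res2$removed_subjects, 0L)

  expect_error(filter_missingness(matrix(NA_real_, 2, 2,
                                         dimnames = list(c("a", "b"),
                                                         c("x", "y")))),
               "removed all")
})

test_that("kNN imputation averages the nearest probes", {
  base <- matrix(rep(seq(0.1, 0.9, by = 0.1), each = 6), nrow = 9,
                 byrow = TRUE,
                 dimnames = list(paste0("cg", 1:9), paste0("s", 1:6)))
  base <- base + matrix(seq(0, 0.05, length.out = 54), nrow = 9)
  x <- base
  x["cg5", "s3"] <- NA
  # k = 1: the single nearest probe's value at s3
  d <- apply(base[-5, ], 1, function(r) mean((r[-3] - base["cg5", -3])^2))
  nearest <- names(which.min(d))
  imp1 <- impute_knn(x, k = 1L)
  expect_equal(imp1["cg5", "s3"], base[nearest, "s3"])
  # k = 2: mean of the two nearest
  two <- names(sort(d))[1:2]
  imp2 <- impute_knn(x, k = 2L)
  expect_equal(imp2["cg5", "s3"], mean(base[two, "s3"]))
  # complete matrix untouched
  expect_identical(impute_knn(base), base)
  # imputed values stay inside [0, 1]
  expect_true(all(imp2 >= 0 & imp2 <= 1))
})

test_that("beta/M transforms are exact and mutually inverse", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  expect_equal(beta_to_m(0.2), -2)
  b <- seq(0.01, 0.99, by = 0.01)
  expect_equal(m_to_beta(beta_to_m(b)), b, tolerance = 1e-9)
  expect_true(is.na(beta_to_m(NA_real_)))
  # boundary clipping keeps the transform finite
  expect_true(is.finite(beta_to_m(0)) && is.finite(beta_to_m(1)))
})

test_that("QC chain is idempotent on a clean matrix", {
  beta <- toy_beta()
  detp <- matrix(0.001, 3, 4, dimnames = dimnames(beta))
  once <- impute_knn(filter_missingness(
    apply_detection_mask(beta, detp))$beta)
  twice <- impute_knn(filter_missingness(
    apply_detection_mask(once, detp))$beta)
  expect_equal(once, twice)
  expect_equal(once, beta)
})

test_that("sample sheet validation names the offending pair", {
  sheet <- toy_sheet()
  validate_sample_sheet(sheet)
  bad <- sheet
  bad$role[2] <- "case"
  expect_error(validate_sample_sheet(bad), "p1")
  bad2 <- sheet
  bad2$sex[1] <- "M"
  expect_error(validate_sample_sheet(bad2), "mismatched sex")
  bad3 <- rbind(sheet, sheet[1, ])
  expect_error(validate_sample_sheet(bad3), "duplicate")
})

test_that("read_inputs aligns axes and drops unmatched subjects with warning", {
  sim <- tiny_cohort(seed = 9)
  dir <- withr::local_tempdir()
  paths <- write_fixture(sim[c("beta", "sheet", "truth", "cell_reference")],
                         sim$manifest, dir)
  # an extra subject in the sheet is dropped with a warning
  sheet2 <- rbind(sim$sheet,
                  data.frame(subject_id = "ghost", pair_id = "PX",
                             role = "case", sex = "F", plate = "plate1",
                             chip = "cX"))
  # orphan pair PX must also fail pairing after the drop -> make it complete
  sheet2 <- rbind(sheet2,
                  data.frame(subject_id = "ghost2", pair_id = "PX",
                             role = "control", sex = "F", plate = "plate2",
                             chip = "cX"))
  p2 <- file.path(dir, "samples2.csv")
  data.table::fwrite(sheet2, p2)
  expect_warning(io <- read_inputs(paths[["beta"]], p2, paths[["manifest"]]),
                 "dropping")
  expect_equal(ncol(io$beta), nrow(sim$sheet))
  expect_false("ghost" %in% io$sheet$subject_id)
  expect_error(read_inputs("no/such/file.tsv", p2, paths[["manifest"]]),
               "not found")
})

test_that("pairs with elevated mean detection p are flagged", {
  sheet <- toy_sheet()
  detp <- matrix(0.001, nrow = 5, ncol = 4,
                 dimnames = list(paste0("cg", 1:5), sheet$subject_id))
  detp[, "s3"] <- 0.2  # one member fails the absolute rule
  flagged <- flag_failed_pairs(sheet, detp)
  expect_equal(unique(flagged$pair_id[flagged$qc_fail]), "p2")
  expect_false(any(flagged$qc_fail[flagged$pair_id == "p1"]))
  clean <- flag_failed_pairs(sheet, detp * 0 + 0.001)
  expect_false(any(clean$qc_fail))
  expect_warning(noop <- flag_failed_pairs(sheet, NULL), "no detection-p")
  expect_false(any(noop$qc_fail))
})
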