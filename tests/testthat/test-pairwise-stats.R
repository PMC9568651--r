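test_that("delta-beta is case minus control with missing propagation", {
  beta <- toy_beta()
  sheet <- toy_sheet()
  d <- delta_beta(beta, sheet)
  expect_equal(dim(d), c(3L, 2L))
  expect_equal(d["cg1", "p1"], 0.2)
  expect_equal(d["cg3", "p2"], -0.05)
  beta2 <- beta
  beta2["cg1", "s1"] <- NA
  expect_true(is.na(delta_beta(beta2, sheet)["cg1", "p1"]))
  expect_error(delta_beta(beta[, 1:3], sheet), "absent")
  # conservation: per-probe sums over pairs equal case minus control sums
  cases <- sheet$subject_id[sheet$role == "case"]
  ctrls <- sheet$subject_id[sheet$role == "control"]
  expect_equal(rowSums(d),
               rowSums(beta[, cases]) - rowSums(beta[, ctrls]))
})

test_that("recurrence screen is inclusive at the threshold and monotone", {
  d <- matrix(0, nrow = 3, ncol = 4,
              dimnames = list(c("cgA", "cgB", "cgC"), paste0("p", 1:4)))
  d["cgA", c(1, 3)] <- c(0.15, -0.15)   # exactly at threshold, two pairs
  d["cgB", 2] <- 0.30                   # one pair only
  res <- recurrent_variable_probes(d)
  expect_equal(res$recurrent_probes, "cgA")
  expect_equal(res$report$n_pairs_exceeding,
               c(2L, 1L, 0L), ignore_attr = TRUE)
  # strict counts differ at the boundary
  expect_equal(res$report$n_pairs_exceeding_strict[1], 0L)
  expect_equal(res$n_exceeding_probes, 2L)
  # monotone: a higher threshold never grows the set
  for (th in c(0.1, 0.2, 0.31)) {
    r_lo <- recurrent_variable_probes(d, threshold = th)
    r_hi <- recurrent_variable_probes(d, threshold = th + 0.05)
    expect_true(all(r_hi$recurrent_probes %in% r_lo$recurrent_probes))
  }
  expect_length(recurrent_variable_probes(d * 0)$recurrent_probes, 0L)
})

test_that("recurrent probes aggregate to genes once per gene", {
  d <- matrix(0.2, nrow = 3, ncol = 2,
              dimnames = list(c("cgA", "cgB", "cgC"), c("p1", "p2")))
  man <- data.frame(probe_id = c("cgA", "cgB", "cgC"),
                    gene = c("G1;G2", "G2", NA))
  res <- recurrent_variable_probes(d, manifest = man)
  expect_equal(res$recurrent_genes, c("G1", "G2"))
})

test_that("pair correlations behave at the extremes", {
  beta <- matrix(c(0.1, 0.2, 0.3, 0.4,
                   0.1, 0.2, 0.3, 0.4,
                   0.4, 0.3, 0.2, 0.1,
                   0.5, 0.5, 0.5, 0.5), nrow = 4,
                 dimnames = list(paste0("cg", 1:4), NULL))
  # identical vectors
  sheet1 <- toy_sheet()
  b1 <- cbind(beta[, 1], beta[, 2], beta[, 3], beta[, 3])
  dimnames(b1) <- list(paste0("cg", 1:4), sheet1$subject_id)
  b1[, "s2"] <- b1[, "s1"]
  pc <- pair_correlation(b1, sheet1)
  expect_equal(pc$correlation[pc$pair_id == "p1"], 1)
  # reversed ranks
  b1[, "s4"] <- rev(b1[, "s3"])
  pc2 <- pair_correlation(b1, sheet1)
  expect_equal(pc2$correlation[pc2$pair_id == "p2"], -1)
  # constant vector is flagged, not an error
  b1[, "s1"] <- 0.5
  b1[, "s2"] <- beta[, 2]
  expect_warning(pc3 <- pair_correlation(b1, sheet1), "constant")
  expect_true(is.na(pc3$correlation[pc3$pair_id == "p1"]))
})

test_that("global content uses the per-subject median and an exact paired test", {
  beta <- matrix(c(0.2, 0.9, 0.95), nrow = 3, ncol = 4,
                 dimnames = list(paste0("cg", 1:3), toy_sheet()$subject_id))
  g <- global_content(beta, toy_sheet())
  expect_true(all(g$per_subject$content == 0.9))
  expect_equal(g$p.value, 1)

  # ten pairs, case median uniformly 0.01 lower: p = 2 * 2^-10
  n <- 10
  sheet <- data.frame(subject_id = paste0("u", 1:(2 * n)),
                      pair_id = rep(sprintf("w%02d", 1:n), each = 2),
                      role = rep(c("case", "control"), n),
                      sex = "F", plate = rep(c("plate1", "plate2"), n),
                      chip = "c")
  base <- seq(0.3, 0.8, length.out = 50)
  beta2 <- sapply(seq_len(2 * n), function(i) {
    pair <- (i + 1) %/% 2
    base + ifelse(i %% 2 == 1, -0.01 - pair * 1e-4, 0)
  })
  dimnames(beta2) <- list(sprintf("cg%02d", 1:50), sheet$subject_id)
  g2 <- global_content(beta2, sheet)
  expect_equal(g2$p.value, 2 * 2^-10, tolerance = 1e-12)
  expect_true(all(g2$case_minus_control < 0))
  # mean variant is exposed
  g3 <- global_content(beta2, sheet, statistic = "mean")
  expect_equal(g3$per_subject$content[1], mean(beta2[, 1]))
})
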