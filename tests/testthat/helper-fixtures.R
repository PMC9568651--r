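# Small in-code fixtures shared across test files.

# tiny cohort: fast enough for per-test regeneration
tiny_config <- function(seed = 1L, ...) {
  args <- modifyList(list(n_pairs = 10L, n_probes = 600L, n_dmrs = 0L,
                          n_cell_probes = 60L, seed = seed), list(...))
  do.call(sim_config, args)
}

tiny_cohort <- function(seed = 1L, ...) {
  cfg <- tiny_config(seed = seed, ...)
  man <- generate_manifest(cfg)
  sim <- generate_cohort(cfg, man)
  c(sim, list(manifest = man, cfg = cfg))
}

# hand-built 2-pair sample sheet
toy_sheet <- function() {
  data.frame(
    subject_id = c("s1", "s2", "s3", "s4"),
    pair_id = c("p1", "p1", "p2", "p2"),
    role = c("case", "control", "case", "control"),
    sex = c("F", "F", "M", "M"),
    plate = c("plate1", "plate2", "plate2", "plate1"),
    chip = c("c1", "c2", "c2", "c1"),
    stringsAsFactors = FALSE)
}

toy_beta <- function() {
  m <- matrix(c(0.80, 0.60, 0.30, 0.35,
                0.10, 0.12, 0.95, 0.90,
                0.50, 0.50, 0.50, 0.55),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("cg1", "cg2", "cg3"),
                              c("s1", "s2", "s3", "s4")))
  m
}

# brute-force two-sided signed-rank p by enumerating all sign patterns
enumerate_signed_rank_p <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  r <- rank(abs(x))
  v_obs <- sum(r[x > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  lower <- mean(v_all <= v_obs)
  upper <- mean(v_all >= v_obs)
  min(1, 2 * min(lower, upper))
}
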