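config300 <- sim_config(seed = 5, enhancer_len = 300L)

test_that("gained trios plant a motif recoverable only in human", {
  for (s in c(11, 12, 13)) {
    tr <- simulate_trio(config300, "gained", seed = s)
    p <- config300$activator_pwms[[1]]
    expect_gte(nrow(scan_pwm(tr$human_seq, p)), 1L)
    expect_equal(nrow(scan_pwm(tr$macaque_seq, p)), 0L)
    expect_equal(nrow(scan_pwm(tr$ancestor_seq, p)), 0L)
    expect_length(tr$essential_positions, 1L)
    expect_true(all(tr$essential_positions %in% tr$mutations$position))
  }
})

test_that("trio sequences differ exactly at the recorded mutations", {
  for (st in c("gained", "lost", "conserved", "neutral")) {
    tr <- simulate_trio(config300, st, seed = 21)
    h <- strsplit(tr$human_seq, "")[[1]]
    m <- strsplit(tr$macaque_seq, "")[[1]]
    expect_identical(which(h != m), as.integer(tr$mutations$position))
    expect_identical(nchar(tr$ancestor_seq), nchar(tr$human_seq))
  }
})

test_that("lost and conserved trios have the intended scan pattern", {
  p <- config300$activator_pwms[[1]]
  lost <- simulate_trio(config300, "lost", seed = 3)
  expect_equal(nrow(scan_pwm(lost$human_seq, p)), 0L)
  expect_gte(nrow(scan_pwm(lost$macaque_seq, p)), 1L)
  expect_gte(nrow(scan_pwm(lost$ancestor_seq, p)), 1L)
  cons <- simulate_trio(config300, "conserved", seed = 3)
  expect_gte(min(nrow(scan_pwm(cons$human_seq, p)),
                 nrow(scan_pwm(cons$macaque_seq, p)),
                 nrow(scan_pwm(cons$ancestor_seq, p))), 1L)
  neut <- simulate_trio(config300, "neutral", seed = 3)
  expect_equal(nrow(scan_pwm(neut$human_seq, p)), 0L)
  expect_length(neut$essential_positions, 0L)
})

test_that("the generator is deterministic under a fixed seed", {
  a <- simulate_trio(config300, "gained", seed = 99)
  b <- simulate_trio(config300, "gained", seed = 99)
  expect_identical(a, b)
  ra <- simulate_het_reads(config300, 50, imbalanced = TRUE, seed = 4)
  rb <- simulate_het_reads(config300, 50, imbalanced = TRUE, seed = 4)
  expect_identical(ra, rb)
  sa <- simulate_mk_sites(c(x = 30, fourfold_background = 30),
                          c(x = 0.5, fourfold_background = 0.5), seed = 4)
  sb <- simulate_mk_sites(c(x = 30, fourfold_background = 30),
                          c(x = 0.5, fourfold_background = 0.5), seed = 4)
  expect_identical(sa, sb)
})

test_that("mutation counts track the Poisson substitution rate", {
  set.seed(17)
  trios <- simulate_trio_set(sim_config(seed = 17, enhancer_len = 200L),
                             rep("neutral", 1000))
  counts <- vapply(trios, function(t) nrow(t$mutations), 0L)
  mu <- 50 * 200 / 1000
  se <- sqrt(mu / 1000)
  expect_lt(abs(mean(counts) - mu), 3 * se)
})

test_that("allele read fractions follow the configured imbalance ratio", {
  cfg <- sim_config(seed = 1, read_depth = 30L, imbalance_ratio = 4)
  bal <- simulate_het_reads(cfg, 10000, imbalanced = FALSE, seed = 2)
  fr_bal <- sum(bal$reads_h) / sum(bal$reads_h + bal$reads_m)
  se <- sqrt(0.25 / (10000 * 30))
  expect_lt(abs(fr_bal - 0.5), 3 * se)
  imb <- simulate_het_reads(cfg, 10000, imbalanced = TRUE, seed = 3)
  fr_imb <- sum(imb$reads_h) / sum(imb$reads_h + imb$reads_m)
  se4 <- sqrt(0.8 * 0.2 / (10000 * 30))
  expect_lt(abs(fr_imb - 0.8), 3 * se4)
})

test_that("MK site simulation respects fixed fractions and empty classes", {
  s <- simulate_mk_sites(c(a = 50, b = 0),
                         c(a = 1.0, b = 0.3), seed = 9)
  expect_true(all(s$fixed[s$class == "a"]))   # fraction 1 => no Pn
  expect_false("b" %in% s$class)              # n = 0 => empty
  expect_true(all(is.na(s$daf) == s$fixed))
  expect_error(simulate_mk_sites(c(a = 5), c(a = 1.5)), "\\[0, 1\\]")
  empty <- simulate_mk_sites(c(a = 0), c(a = 0.5))
  expect_equal(nrow(empty), 0L)
})

test_that("expression simulation correlates linked pairs and not others", {
  edges <- data.frame(source = "A", target = "B")
  tfs <- c("A", "B", "C")
  # near-zero noise: regulated TF tracks its regulator almost exactly
  e0 <- simulate_expression(edges, tfs, n_samples = 100, noise_sd = 1e-6,
                            seed = 2)
  expect_gt(cor(e0["A", ], e0["B", ], method = "spearman"), 0.99)
  # unlinked pairs stay below the coexpression cutoff in most seeds
  below <- vapply(1:40, function(s) {
    e <- simulate_expression(edges, tfs, n_samples = 500, noise_sd = 0.3,
                             seed = s)
    abs(cor(e["A", ], e["C", ], method = "spearman")) < 0.3
  }, TRUE)
  expect_gte(mean(below), 0.95)
  expect_warning(simulate_expression(edges, tfs, n_samples = 2),
                 "samples")
})
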