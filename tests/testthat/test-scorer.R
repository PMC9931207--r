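test_that("count_parameters follows the layer arithmetic", {
  # single conv layer: 4*5*8 + 8 = 168, plus a 1-unit dense head
  cfg <- model_config(20L, 8L, 5L, 16L, dense_units = 1L,
                      output_units = 1L)
  # flat length: (20-5+1)=16, pool 16 -> 1, so dense = 8*1+1, out = 1+1
  expect_equal(count_parameters(cfg), 168L + 9L + 2L)
  # doubling kernel count doubles the conv weight+bias contribution
  cfg2 <- model_config(20L, 16L, 5L, 16L, dense_units = 1L,
                       output_units = 1L)
  conv1 <- count_parameters(cfg) - (8 * 1 + 1) - 2
  conv2 <- count_parameters(cfg2) - (16 * 1 + 1) - 2
  expect_equal(conv2, 2L * conv1)
  # invalid: pooling below length 1
  expect_error(model_config(10L, 8L, 5L, 7L), "below 1")
})

test_that("count_parameters equals the instantiated network's own total", {
  set.seed(42)
  for (i in 1:20) {
    nl <- sample(1:3, 1)
    cfg <- NULL
    while (is.null(cfg)) {
      cand <- try(model_config(sample(40:200, 1), sample(4:24, nl),
                               sample(3:9, nl), sample(1:3, nl),
                               sample(4:32, 1), sample(1:2, 1)),
                  silent = TRUE)
      if (!inherits(cand, "try-error")) cfg <- cand
    }
    net <- enhgain:::nn_init(cfg, seed = i)
    expect_identical(count_parameters(cfg), enhgain:::nn_num_params(net))
  }
})

test_that("the architecture solver finds and rejects small targets correctly", {
  # target achievable only at width 5, pool 8 (flat length 2)
  sol <- solve_reference_architecture(
    target_params = 187L, conv_kernels = 8L, dense_units = 1L,
    input_len = 20L, width_range = 2:26, pool_range = 1:8,
    output_range = 1L)
  expect_equal(sol$kernel_widths, 5L)
  expect_equal(count_parameters(sol), 187L)
  # 188 is unreachable: totals are 32w + 8L + 11 with parity fixed
  expect_message(
    sol2 <- solve_reference_architecture(
      target_params = 188L, conv_kernels = 8L, dense_units = 1L,
      input_len = 20L, width_range = 2:26, pool_range = 1:8,
      output_range = 1L),
    "no architecture")
  expect_null(sol2)
})

test_that("the frozen reference architecture has the full-scale parameter count", {
  expect_equal(count_parameters(reference_config()), 3631401L)
})

test_that("calibrate_threshold picks the smallest admissible order statistic", {
  thr <- calibrate_threshold(seq(0.01, 0.10, by = 0.01), fpr = 0.1)
  expect_equal(thr$value, 0.10)
  # fpr 1: everything may pass, threshold is the minimum score
  expect_equal(calibrate_threshold(seq(0.01, 0.10, by = 0.01),
                                   fpr = 1)$value, 0.01)
  # all-equal scores: nothing may pass at 10% FPR
  suppressWarnings(
    thr_eq <- calibrate_threshold(rep(0.5, 20), fpr = 0.1))
  expect_gt(thr_eq$value, 0.5)
  expect_error(calibrate_threshold(numeric(0)), "no negative scores")
})

test_that("calibrated thresholds hit their empirical FPR and are monotone in fpr", {
  set.seed(8)
  for (rep in 1:5) {
    scores <- runif(500)
    fprs <- c(0.01, 0.05, 0.1, 0.25, 0.5)
    thrs <- vapply(fprs, function(f) {
      calibrate_threshold(scores, f)$value
    }, 0)
    for (j in seq_along(fprs)) {
      expect_lte(mean(scores >= thrs[j]), fprs[j])
    }
    expect_true(all(diff(thrs) <= 0))  # non-increasing threshold in fpr
  }
})

test_that("scores are exactly reverse-complement invariant and bounded", {
  sc <- make_untrained_scorer(model_config(60L, 8L, 5L, 14L, 8L), seed = 3)
  set.seed(4)
  seqs <- enhgain:::random_dna(10, 60)
  s_f <- score(sc, seqs)
  s_r <- score(sc, revcomp(seqs))
  expect_identical(s_f, s_r)
  expect_true(all(s_f >= 0 & s_f <= 1))
  # all-N input scores under the uniform encoding, still in [0,1]
  sN <- score(sc, strrep("N", 60))
  expect_true(sN >= 0 && sN <= 1)
  expect_error(score(sc, "ACGT"), "length")
})

test_that("delta_score is zero on empty edits and cancels on revert", {
  seqs <- "ACGTACGTACGTACGTACGT"
  expect_identical(delta_score(toy_scorer, seqs, integer(0), character(0)),
                   0)
  d1 <- delta_score(toy_scorer, seqs, 1L, "T")
  edited <- enhgain:::apply_edits(seqs, 1L, "T")
  d2 <- delta_score(toy_scorer, edited, 1L, "A")
  expect_equal(d1 + d2, 0)
  # motif-completing edit raises the score
  p <- toy_pwms[[1]]
  key <- enhgain:::pwm_key_position(p)
  broken <- strsplit(pwm_consensus(p), "")[[1]]
  broken[key$pos] <- key$broken
  s <- paste0("TTTTT", paste(broken, collapse = ""), "TTTTTTT")
  d <- delta_score(toy_scorer, s, 5L + key$pos, key$consensus)
  expect_gt(d, 0)
  expect_error(delta_score(toy_scorer, s, 999L, "A"), "out of range")
})

test_that("allele-direction accuracy is 1 on concordant pairs and 0.5 on noise", {
  d <- c(-0.4, 0.2, 0.6, -0.1)
  lab <- sign(d)
  curve <- allele_effect_accuracy(d, lab, margins = c(0, 0.1, 0.3))
  expect_true(all(curve$accuracy == 1))
  expect_equal(curve$coverage, c(1, 1, 0.5))
  set.seed(6)
  d2 <- rnorm(10000)
  lab2 <- sample(c(-1, 1), 10000, replace = TRUE)
  c2 <- allele_effect_accuracy(d2, lab2, margins = 0)
  expect_lt(abs(c2$accuracy - 0.5), 0.02)
  # margin above max |delta|: point undefined
  c3 <- allele_effect_accuracy(d, lab, margins = 10)
  expect_true(is.na(c3$accuracy))
})

test_that("training is seed-reproducible and errors on missing classes", {
  d <- simulate_training_set(80, 80, len = 80, seed = 2)
  cfg <- model_config(80L, 12L, 9L, 72L, 8L)
  f1 <- enhancer_cnn(d$seq, d$label, d$chrom, config = cfg, seed = 7,
                     epochs = 3)
  f2 <- enhancer_cnn(d$seq, d$label, d$chrom, config = cfg, seed = 7,
                     epochs = 3)
  expect_identical(f1$metrics, f2$metrics)
  expect_identical(f1$net, f2$net)
  # all positives on chr8/9: training split would lack a class
  chrom_bad <- ifelse(d$label == 1, "chr8", "chr1")
  expect_error(enhancer_cnn(d$seq, d$label, chrom_bad, config = cfg),
               "does not contain both classes")
})
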