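cfg300 <- sim_config(seed = 2, enhancer_len = 300L)

test_that("single-mutation effects recover the planted essential site", {
  tr <- simulate_trio(cfg300, "gained", seed = 41)
  eff <- single_mutation_effects(toy_scorer, tr$macaque_seq,
                                 tr$mutations, 0.5)
  expect_identical(eff$position[eff$essential], tr$essential_positions)
  # non-essential flanking alleles barely move the score
  expect_true(all(abs(eff$delta[!eff$essential]) < 0.4))
  # empty mutation list is fine
  e0 <- single_mutation_effects(toy_scorer, tr$macaque_seq,
                                tr$mutations[0, ], 0.5)
  expect_equal(nrow(e0), 0L)
  # an already-active start is rejected
  expect_error(single_mutation_effects(toy_scorer, tr$human_seq,
                                       tr$mutations, 0.5),
               "already active")
})

test_that("introducing all alleles reconstructs the human sequence and its score", {
  tr <- simulate_trio(cfg300, "gained", seed = 42)
  full <- enhgain:::apply_edits(tr$macaque_seq, tr$mutations$position,
                                tr$mutations$human_allele)
  expect_identical(full, tr$human_seq)
  d <- delta_score(toy_scorer, tr$macaque_seq, tr$mutations$position,
                   tr$mutations$human_allele)
  expect_identical(d, score(toy_scorer, tr$human_seq) -
                     score(toy_scorer, tr$macaque_seq))
})

test_that("minimal-set search matches exhaustive enumeration on planted cases", {
  tr <- simulate_trio(cfg300, "gained", seed = 43)
  ms <- find_minimal_activating_set(toy_scorer, tr$macaque_seq,
                                    tr$mutations, 0.5, cap = Inf)
  expect_equal(ms$m, 1L)
  expect_identical(ms$combination$position, tr$essential_positions)
  oracle <- exhaustive_minimal_set(toy_scorer, tr$macaque_seq,
                                   tr$mutations, 0.5)
  expect_equal(ms$m, oracle$m)
  expect_identical(ms$combination$position, oracle$positions)
})

test_that("a jointly-required pair is found at m = 2 by exhaustive pairs", {
  # break the motif at two positions; both restoring alleles are needed
  p <- toy_pwms[[1]]
  cons <- strsplit(pwm_consensus(p), "")[[1]]
  broken <- cons
  broken[c(2, 7)] <- c("T", "C")
  stopifnot(!identical(broken[2], cons[2]), !identical(broken[7], cons[7]))
  base <- paste0(strrep("T", 20), paste(broken, collapse = ""),
                 strrep("T", 20))
  muts <- data.frame(position = c(5L, 22L, 27L, 40L),
                     human_allele = c("G", cons[2], cons[7], "C"),
                     stringsAsFactors = FALSE)
  ms <- find_minimal_activating_set(toy_scorer, base, muts, 0.5,
                                    cap = Inf)
  expect_equal(ms$m, 2L)
  expect_setequal(ms$combination$position, c(22L, 27L))
  oracle <- exhaustive_minimal_set(toy_scorer, base, muts, 0.5)
  expect_equal(oracle$m, 2L)
  expect_setequal(oracle$positions, c(22L, 27L))
})

test_that("combination unranking reproduces lexicographic enumeration", {
  want <- combn(6, 3)
  got <- vapply(seq_len(ncol(want)),
                enhgain:::unrank_combination, integer(3), n = 6, m = 3)
  expect_identical(got, want)
})

test_that("the sampling cap limits evaluations reproducibly", {
  set.seed(30)
  base <- enhgain:::random_dna(1, 60)
  counter <- make_edit_count_scorer(base, need = 2L)
  bases <- c("A", "C", "G", "T")
  ref <- strsplit(base, "")[[1]]
  pos <- seq(3L, 57L, by = 5L)  # 11 mutations
  muts <- data.frame(position = pos,
                     human_allele = vapply(pos, function(i) {
                       setdiff(bases, ref[i])[1]
                     }, ""), stringsAsFactors = FALSE)
  # C(11,2) = 55 > cap 40: sampled without replacement, any pair works
  ms <- find_minimal_activating_set(counter, base, muts, 0.5, cap = 40,
                                    seed = 5)
  expect_equal(ms$m, 2L)
  expect_true(ms$capped)
  expect_equal(ms$n_evaluated, 40L)
  ms2 <- find_minimal_activating_set(counter, base, muts, 0.5, cap = 40,
                                     seed = 5)
  expect_identical(ms, ms2)
  # uncapped: enumeration, no flag
  ms3 <- find_minimal_activating_set(counter, base, muts, 0.5, cap = Inf)
  expect_false(ms3$capped)
  expect_equal(ms3$n_evaluated, 55L)
})

test_that("a never-activating mutation set reports an absent minimal size", {
  tr <- simulate_trio(cfg300, "neutral", seed = 44)
  muts <- tr$mutations[seq_len(min(6, nrow(tr$mutations))), ]
  ms <- find_minimal_activating_set(toy_scorer, tr$macaque_seq, muts, 0.5)
  expect_true(is.na(ms$m))
})

test_that("deactivating-essential mirrors the gain test", {
  tr <- simulate_trio(cfg300, "gained", seed = 45)
  p <- toy_pwms[[1]]
  key <- enhgain:::pwm_key_position(p)
  ep <- tr$essential_positions
  # reverting the essential allele back to the broken base deactivates
  expect_true(deactivating_essential(toy_scorer, tr$human_seq, ep,
                                     key$broken, 0.5))
  # a flank variant does not
  flank <- setdiff(seq_len(50), tr$motif_offset:(tr$motif_offset + 7))[1]
  ref <- substr(tr$human_seq, flank, flank)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  expect_false(deactivating_essential(toy_scorer, tr$human_seq, flank,
                                      alt, 0.5))
  # the reference allele is not a variant
  expect_error(deactivating_essential(toy_scorer, tr$human_seq, flank,
                                      ref, 0.5), "reference")
  # an inactive start is rejected
  expect_error(deactivating_essential(toy_scorer, tr$macaque_seq, ep,
                                      "A", 0.5), "not active")
})
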