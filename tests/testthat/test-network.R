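# Build region sequences with or without a planted consensus, rejecting
# accidental hits in the unplanted ones.
plant_regions <- function(n_hit, n_miss, p, len = 60) {
  hit <- vapply(seq_len(max(n_hit, 0)), function(i) {
    s <- strsplit(enhgain:::random_dna(1, len), "")[[1]]
    o <- sample(len - nrow(p$matrix), 1)
    s[o:(o + nrow(p$matrix) - 1)] <- strsplit(pwm_consensus(p), "")[[1]]
    paste(s, collapse = "")
  }, "")
  miss <- vapply(seq_len(max(n_miss, 0)), function(i) {
    repeat {
      s <- enhgain:::random_dna(1, len)
      if (nrow(scan_pwm(s, p)) == 0) return(s)
    }
  }, "")
  c(hit, miss)
}

test_that("motif enrichment reproduces the odds-ratio arithmetic", {
  p <- toy_pwms[[1]]
  set.seed(51)
  fg <- plant_regions(50, 50, p)
  bg <- plant_regions(10, 90, p)
  enr <- motif_enrichment(fg, bg, p)
  expect_equal(enr$fg_hit, 50)
  expect_equal(enr$bg_hit, 10)
  expect_equal(enr$odds_ratio, (50 * 90) / (50 * 10))
  expect_equal(enr$p_value, enum_fisher_p(50, 50, 10, 90),
               tolerance = 1e-10)
  # identical sets: no association
  same <- motif_enrichment(fg, fg, p)
  expect_equal(same$odds_ratio, 1)
  expect_equal(same$p_value, 1)
  # extreme separation: enumeration gives the two-tail extreme p
  ext <- motif_enrichment(plant_regions(20, 0, p),
                          plant_regions(0, 20, p), p)
  expect_equal(ext$p_value, enum_fisher_p(20, 0, 0, 20),
               tolerance = 1e-12)
  expect_error(motif_enrichment(character(0), bg, p), "non-empty")
})

test_that("site gain/loss reflects which allele completes the motif", {
  p <- toy_pwms[[1]]
  key <- enhgain:::pwm_key_position(p)
  cons <- strsplit(pwm_consensus(p), "")[[1]]
  s <- strsplit(paste0(strrep("T", 12), pwm_consensus(p),
                       strrep("T", 12)), "")[[1]]
  pos <- 12L + key$pos
  # human allele = consensus, macaque allele = broken: gain
  expect_equal(site_gain_loss(paste(s, collapse = ""), pos,
                              key$consensus, key$broken, p), "gain")
  expect_equal(site_gain_loss(paste(s, collapse = ""), pos,
                              key$broken, key$consensus, p), "loss")
  # both alleles break the motif: neutral
  other <- setdiff(c("A", "C", "G", "T"), c(key$consensus, key$broken))
  expect_equal(site_gain_loss(paste(s, collapse = ""), pos,
                              other[1], other[2], p), "neutral")
  expect_error(site_gain_loss("ACGT", 9L, "A", "C", p), "outside")
})

test_that("TF roles follow the 1.2-fold gain/loss rule with pseudocounts", {
  expect_equal(classify_tf_role(30, 10, 20, 10), "activator")
  expect_equal(classify_tf_role(10, 30, 10, 20), "repressor")
  expect_equal(classify_tf_role(10, 10, 10, 10), "undetermined")
  # pseudocounts keep zero denominators finite
  expect_equal(classify_tf_role(10, 0, 1, 1), "activator")
  expect_equal(classify_tf_role(0, 10, 1, 1), "repressor")
  expect_error(classify_tf_role(-1, 1, 1, 1), "non-negative")
})

test_that("network inference recovers planted edges and only those", {
  set.seed(61)
  pA <- toy_pwms[[1]]; pB <- toy_pwms[[2]]
  pwms <- list(TFA = pA, TFB = pB)
  # planted truth: TFA regulates geneB (dense TFA motifs in geneB's
  # gained enhancers only); no other edges
  gained <- list(
    geneA = plant_regions(0, 4, pA),
    geneB = vapply(1:4, function(i) {
      paste0(plant_regions(1, 0, pA, len = 40),
             plant_regions(1, 0, pA, len = 40))
    }, ""))
  conserved <- list(geneA = plant_regions(0, 4, pA),
                    geneB = plant_regions(0, 4, pA))
  # remove accidental TFB hits from every region set
  strip_hits <- function(seqs, p) {
    vapply(seqs, function(s) {
      while (nrow(scan_pwm(s, p)) > 0) s <- enhgain:::random_dna(1, nchar(s))
      s
    }, "", USE.NAMES = FALSE)
  }
  gained$geneA <- strip_hits(gained$geneA, pB)
  conserved$geneA <- strip_hits(conserved$geneA, pB)
  conserved$geneB <- strip_hits(conserved$geneB, pB)
  net <- build_network(gained, conserved, pwms)
  expect_equal(nrow(net), 1L)
  expect_equal(net$source, "TFA")
  expect_equal(net$target, "geneB")
  # no planted motifs anywhere: empty network
  none <- build_network(list(g = plant_regions(0, 3, pA)),
                        list(g = plant_regions(0, 3, pA)), pwms["TFA"])
  expect_equal(nrow(none), 0L)
  # equal density in both sets: no edge
  eq <- build_network(list(g = plant_regions(3, 0, pA)),
                      list(g = plant_regions(3, 0, pA)), pwms["TFA"])
  expect_equal(nrow(eq), 0L)
  # a target without conserved enhancers is skipped with a warning
  expect_warning(build_network(list(g = plant_regions(1, 0, pA)),
                               list(g = character(0)), pwms["TFA"]),
                 "skipped")
})

test_that("hierarchy counts degrees, ranks and the master regulator", {
  edges <- data.frame(source = c("A", "A", "B"),
                      target = c("B", "C", "A"))
  h <- hierarchy(edges)
  expect_equal(h$master, "A")
  d <- h$degrees
  expect_equal(d$out_degree[d$tf == "A"], 2L)
  expect_equal(d$out_degree[d$tf == "C"], 0L)
  expect_equal(d$in_degree[d$tf == "A"], 1L)
  # self-edge counts in both directions
  h2 <- hierarchy(data.frame(source = "A", target = "A"))
  expect_equal(h2$degrees$out_degree, 1L)
  expect_equal(h2$degrees$in_degree, 1L)
  # empty network: all degrees zero, master undefined
  h0 <- hierarchy(edges[0, ], tfs = c("X", "Y"))
  expect_true(all(h0$degrees$out_degree == 0))
  expect_true(is.na(h0$master))
  # ties broken lexicographically
  h3 <- hierarchy(data.frame(source = c("B", "A"), target = c("C", "C")))
  expect_equal(h3$master, "A")
})
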