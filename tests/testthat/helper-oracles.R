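# Independent brute-force oracles and small fixture builders used across
# the suite.  Oracles deliberately avoid the package's own code paths.

# Naive per-window PWM scan: explicit loops, explicit reverse complement.
naive_scan <- function(seq, p, threshold) {
  lo <- enhgain:::pwm_logodds(p)
  w <- nrow(lo)
  bases <- c("A", "C", "G", "T")
  rc1 <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1L]]),
          collapse = "")
  }
  score_window <- function(win) {
    ch <- strsplit(win, "")[[1L]]
    sum(vapply(seq_len(w), function(j) lo[j, match(ch[j], bases)], 0))
  }
  n <- nchar(seq)
  out <- list()
  for (o in 0:(n - w)) {
    win <- substr(seq, o + 1L, o + w)
    sf <- score_window(win)
    if (sf >= threshold) {
      out[[length(out) + 1L]] <- data.frame(offset = o, strand = "+",
                                            score = sf)
    }
    sr <- score_window(rc1(win))
    if (sr >= threshold) {
      out[[length(out) + 1L]] <- data.frame(offset = o, strand = "-",
                                            score = sr)
    }
  }
  if (!length(out)) {
    return(data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0)))
  }
  do.call(rbind, out)
}

# Exhaustive minimal-activating-set search (enumeration only, no cap),
# with the same tie-break: largest delta, then lexicographic positions.
exhaustive_minimal_set <- function(scorer, macaque_seq, mutations, thr) {
  n <- nrow(mutations)
  base <- score(scorer, macaque_seq)
  for (m in seq_len(n)) {
    combos <- combn(n, m)
    if (m == 1L) combos <- matrix(combos, nrow = 1L)
    best <- NULL; best_s <- -Inf
    for (j in seq_len(ncol(combos))) {
      idx <- combos[, j]
      ed <- enhgain:::apply_edits(macaque_seq, mutations$position[idx],
                                  mutations$human_allele[idx])
      s <- score(scorer, ed)
      if (s >= thr && s > best_s) {
        best_s <- s; best <- idx
      }
    }
    if (!is.null(best)) {
      return(list(m = m, positions = mutations$position[best],
                  delta = best_s - base))
    }
  }
  list(m = NA_integer_, positions = integer(0), delta = NA_real_)
}

# Exact two-sided binomial p-value by outcome enumeration (p = 0.5).
enum_binom_p <- function(k, n) {
  probs <- vapply(0:n, function(i) choose(n, i) / 2^n, 0)
  sum(probs[probs <= probs[k + 1L] * (1 + 1e-7)])
}

# Exact two-sided Fisher p-value by hypergeometric table enumeration.
enum_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0L, c1 - (n - r1)); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x) {
    exp(lchoose(r1, x) + lchoose(n - r1, c1 - x) - lchoose(n, c1))
  }, 0)
  obs <- probs[a - lo + 1L]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Untrained CNN scorer (random weights) for contract tests that do not
# need a fitted model.
make_untrained_scorer <- function(config = model_config(), seed = 1L) {
  structure(list(config = config, net = enhgain:::nn_init(config, seed)),
            class = "enhancer_cnn")
}

# Toy scorer that activates once at least `need` edits diverge from the
# stored base sequence; used to exercise the sampling cap deterministically.
make_edit_count_scorer <- function(base_seq, need = 2L) {
  obj <- structure(list(base = base_seq, need = need),
                   class = "edit_count_scorer")
  obj
}
score.edit_count_scorer <- function(object, sequences, ...) {
  b <- strsplit(object$base, "")[[1L]]
  vapply(sequences, function(s) {
    k <- sum(strsplit(s, "")[[1L]] != b)
    1 / (1 + exp(-5 * (k - object$need + 0.5)))
  }, 0, USE.NAMES = FALSE)
}
registerS3method("score", "edit_count_scorer", score.edit_count_scorer,
                 envir = asNamespace("enhgain"))

# A quick default PWM set + scorer shared by several files.
toy_pwms <- example_pwms("activator")
toy_scorer <- pwm_scorer(toy_pwms)
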