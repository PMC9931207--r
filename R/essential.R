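# Lexicographic unranking of the r-th m-combination of 1..n (r is 1-based).
unrank_combination <- function(r, n, m) {
  out <- integer(m)
  x <- 1L
  r <- r - 1
  for (i in seq_len(m)) {
    repeat {
      c_rest <- choose(n - x, m - i)
      if (r < c_rest) break
      r <- r - c_rest
      x <- x + 1L
    }
    out[i] <- x
    x <- x + 1L
  }
  out
}

#' Score the effect of each human allele introduced alone
#'
#' Starting from the (inactive) macaque sequence, introduces each
#' human-specific allele on its own and records the score change.  A
#' mutation is *essential* when it alone activates the enhancer, i.e. the
#' edited score reaches the activity threshold.
#'
#' @param scorer A scorer (see [score()]).
#' @param macaque_seq Macaque ortholog sequence; must score below the
#'   threshold (essentiality is undefined for an already-active start).
#' @param mutations `data.frame` with `position` (1-based) and
#'   `human_allele` (as from [extract_mutations()]).
#' @param threshold A [calibrate_threshold()] result or numeric cutoff.
#' @return `data.frame` with `position`, `human_allele`, `delta`,
#'   `activates`, `essential` (identical to `activates`).
#' @export
single_mutation_effects <- function(scorer, macaque_seq, mutations,
                                    threshold) {
  thr <- thr_value(threshold)
  base <- score(scorer, macaque_seq)
  if (base >= thr) {
    stop("macaque sequence is already active (score ", round(base, 4),
         " >= threshold ", round(thr, 4),
         "); essentiality is undefined")
  }
  if (nrow(mutations) == 0L) {
    return(data.frame(position = integer(0), human_allele = character(0),
                      delta = numeric(0), activates = logical(0),
                      essential = logical(0)))
  }
  edited <- vapply(seq_len(nrow(mutations)), function(i) {
    apply_edits(macaque_seq, mutations$position[i],
                mutations$human_allele[i])
  }, "")
  s <- score(scorer, edited)
  data.frame(position = mutations$position,
             human_allele = mutations$human_allele,
             delta = s - base,
             activates = s >= thr,
             essential = s >= thr,
             stringsAsFactors = FALSE)
}

#' Find the minimal set of human alleles that activates an enhancer
#'
#' Iterates over combination sizes `m = 1, 2, ...`: all `choose(n, m)`
#' combinations of human alleles are introduced into the macaque sequence
#' and scored when their number does not exceed `cap` (default 10,000);
#' otherwise `cap` distinct combinations are sampled without replacement.
#' The first size with an activating combination is returned; among
#' activating combinations of that size the one with the largest score
#' change wins, ties broken by lexicographic position order.
#'
#' @inheritParams single_mutation_effects
#' @param cap Maximum combinations evaluated per size (`Inf` disables
#'   sampling).
#' @param seed Seed for combination sampling.
#' @return Object of class `minimal_set`: `m` (smallest activating size,
#'   `NA` if even all alleles fail), `combination` (rows of `mutations`),
#'   `delta`, `n_evaluated`, `capped`.
#' @export
find_minimal_activating_set <- function(scorer, macaque_seq, mutations,
                                        threshold, cap = 10000L,
                                        seed = 1L) {
  thr <- thr_value(threshold)
  n <- nrow(mutations)
  if (n < 1L) stop("at least one mutation is required")
  base <- score(scorer, macaque_seq)
  if (base >= thr) {
    stop("macaque sequence is already active; nothing to activate")
  }
  set.seed(seed)
  for (m in seq_len(n)) {
    total <- choose(n, m)
    capped <- is.finite(cap) && total > cap
    combos <- if (!capped) {
      combn(n, m)
    } else if (total <= .Machine$integer.max) {
      ranks <- sort(sample.int(as.integer(total), cap))
      vapply(ranks, unrank_combination, integer(m), n = n, m = m)
    } else {
      # combination space too large to index: draw distinct random
      # combinations until `cap` unique ones are collected
      seen <- new.env(hash = TRUE)
      cols <- vector("list", cap)
      got <- 0L
      while (got < cap) {
        cmb <- sort(sample.int(n, m))
        k <- paste(cmb, collapse = ",")
        if (is.null(seen[[k]])) {
          seen[[k]] <- TRUE
          got <- got + 1L
          cols[[got]] <- cmb
        }
      }
      mat <- matrix(unlist(cols), nrow = m)
      mat[, do.call(order, as.data.frame(t(mat))), drop = FALSE]
    }
    if (m == 1L) combos <- matrix(combos, nrow = 1L)
    edited <- vapply(seq_len(ncol(combos)), function(j) {
      idx <- combos[, j]
      apply_edits(macaque_seq, mutations$position[idx],
                  mutations$human_allele[idx])
    }, "")
    s <- score(scorer, edited)
    act <- which(s >= thr)
    if (length(act)) {
      best <- act[which.max(s[act])]
      return(structure(list(
        m = m,
        combination = mutations[combos[, best], , drop = FALSE],
        delta = s[best] - base,
        score = s[best],
        n_evaluated = ncol(combos),
        capped = capped), class = "minimal_set"))
    }
  }
  structure(list(m = NA_integer_, combination = mutations[0, ],
                 delta = NA_real_, score = NA_real_,
                 n_evaluated = NA_integer_, capped = FALSE),
            class = "minimal_set")
}

#' @export
print.minimal_set <- function(x, ...) {
  if (is.na(x$m)) {
    cat("No activating combination found (even with all alleles)\n")
  } else {
    cat(sprintf(
      "Minimal activating set: m = %d (positions %s), delta %.4f%s\n",
      x$m, paste(x$combination$position, collapse = ","), x$delta,
      if (x$capped) sprintf(" [sampled %d combinations]", x$n_evaluated)
      else ""))
  }
  invisible(x)
}

#' Does a single variant alone deactivate an active enhancer?
#'
#' The mirrored test used for de novo variants in active (human)
#' enhancers: a variant is deactivating-essential when introducing it
#' drops the score below the activity threshold.
#'
#' @param scorer A scorer.
#' @param human_seq Active sequence (must score at or above the
#'   threshold).
#' @param position 1-based variant position.
#' @param allele Variant base (must differ from the reference base).
#' @param threshold Threshold object or numeric cutoff.
#' @return Logical.
#' @export
deactivating_essential <- function(scorer, human_seq, position, allele,
                                   threshold) {
  thr <- thr_value(threshold)
  base <- score(scorer, human_seq)
  if (base < thr) {
    stop("sequence is not active (score ", round(base, 4),
         " < threshold); deactivation is undefined")
  }
  edited <- apply_edits(human_seq, position, allele)
  score(scorer, edited) < thr
}
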