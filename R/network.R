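#' Motif enrichment in foreground vs background regions
#'
#' Counts regions containing at least one motif hit in each set and tests
#' the 2x2 table (hit/no-hit by set) with Fisher's exact test.  The odds
#' ratio is the sample cross-product ratio.
#'
#' @param fg_seqs,bg_seqs Character vectors of region sequences (both
#'   non-empty).
#' @param x A calibrated [pwm()].
#' @return List with `fg_hit`, `fg_total`, `bg_hit`, `bg_total`,
#'   `odds_ratio`, `p_value`.
#' @export
motif_enrichment <- function(fg_seqs, bg_seqs, x) {
  if (length(fg_seqs) == 0L || length(bg_seqs) == 0L) {
    stop("both sequence sets must be non-empty")
  }
  fg_hit <- sum(vapply(fg_seqs, function(s) count_hits(s, x) > 0L, TRUE))
  bg_hit <- sum(vapply(bg_seqs, function(s) count_hits(s, x) > 0L, TRUE))
  a <- fg_hit; b <- length(fg_seqs) - fg_hit
  c_ <- bg_hit; d <- length(bg_seqs) - bg_hit
  or <- (a * d) / (b * c_)
  p <- fisher.test(matrix(c(a, b, c_, d), 2L))$p.value
  list(fg_hit = a, fg_total = length(fg_seqs), bg_hit = c_,
       bg_total = length(bg_seqs), odds_ratio = or, p_value = p)
}

#' Classify a substitution as binding-site gain, loss or neutral
#'
#' Scans the sequence context under each allele and compares motif hits
#' overlapping the substitution position: a *gain* has a hit with the
#' human allele but none with the macaque allele, a *loss* the converse.
#'
#' @param seq_context Sequence carrying the macaque allele at `position`
#'   (any allele works; both variants are constructed internally).
#' @param position 1-based substitution position within `seq_context`.
#' @param human_allele,macaque_allele The two bases.
#' @param x A calibrated [pwm()].
#' @return `"gain"`, `"loss"`, or `"neutral"`.
#' @export
site_gain_loss <- function(seq_context, position, human_allele,
                           macaque_allele, x) {
  if (position < 1L || position > nchar(seq_context)) {
    stop("position outside the sequence")
  }
  chars <- strsplit(seq_context, "")[[1L]]
  chars[position] <- macaque_allele
  mseq <- paste(chars, collapse = "")
  chars[position] <- human_allele
  hseq <- paste(chars, collapse = "")
  w <- nrow(x$matrix)
  overlaps <- function(s) {
    h <- scan_pwm(s, x)
    any(h$offset < position & position <= h$offset + w)
  }
  h_hit <- overlaps(hseq)
  m_hit <- overlaps(mseq)
  if (h_hit && !m_hit) "gain" else if (m_hit && !h_hit) "loss" else
    "neutral"
}

#' Classify a TF as activator or repressor from site gain/loss counts
#'
#' A TF is an activator when the gain:loss ratio caused by essential
#' mutations exceeds `fold` times the same ratio for common SNPs, and a
#' repressor when the loss:gain ratio does.  All four counts receive a
#' 0.5 pseudocount (Haldane-Anscombe) so zero denominators stay finite.
#'
#' @param gain_essential,loss_essential Binding-site gains/losses caused
#'   by essential mutations.
#' @param gain_snp,loss_snp The same for common SNPs.
#' @param fold Required fold excess (default 1.2).
#' @return `"activator"`, `"repressor"`, or `"undetermined"`.
#' @examples
#' classify_tf_role(30, 10, 20, 10)  # activator
#' @export
classify_tf_role <- function(gain_essential, loss_essential, gain_snp,
                             loss_snp, fold = 1.2) {
  if (any(c(gain_essential, loss_essential, gain_snp, loss_snp) < 0)) {
    stop("counts must be non-negative")
  }
  ge <- gain_essential + 0.5; le <- loss_essential + 0.5
  gs <- gain_snp + 0.5; ls <- loss_snp + 0.5
  if ((ge / le) > fold * (gs / ls)) "activator"
  else if ((le / ge) > fold * (ls / gs)) "repressor"
  else "undetermined"
}

#' Infer a TF regulatory network from motif density enrichment
#'
#' An edge source TF -> target TF gene is drawn when the density of the
#' source motif (hits per kb, both strands) over the de novo gained
#' enhancers near the target gene is enriched relative to the conserved
#' enhancers near the same gene: fold enrichment at least `ratio_min` and
#' a one-sided binomial p-value at most `p_max` treating the background
#' density as the per-bp hit rate (0.5 pseudo-hit on the background keeps
#' the rate positive).  Self-edges (autoregulation) are allowed.  Target
#' genes lacking gained or conserved enhancers are skipped with a
#' warning.
#'
#' @param gained_by_gene Named list: per target TF gene, a character
#'   vector of gained-enhancer sequences.
#' @param conserved_by_gene Named list with the same names: conserved
#'   (background) enhancer sequences.
#' @param pwms Named list of calibrated [pwm()]s, one per source TF.
#' @param ratio_min Minimum density fold enrichment (default 1.5).
#' @param p_max Maximum one-sided binomial p-value (default 0.05).
#' @return `data.frame` of retained edges: `source`, `target`,
#'   `density_fg`, `density_bg`, `ratio`, `p_value`.
#' @export
build_network <- function(gained_by_gene, conserved_by_gene, pwms,
                          ratio_min = 1.5, p_max = 0.05) {
  targets <- names(gained_by_gene)
  edges <- list()
  for (tg in targets) {
    fg <- gained_by_gene[[tg]]
    bg <- conserved_by_gene[[tg]]
    if (is.null(fg) || length(fg) == 0L || is.null(bg) ||
        length(bg) == 0L) {
      warning("target '", tg,
              "' lacks gained or conserved enhancers; skipped")
      next
    }
    fg_bp <- sum(nchar(fg)); bg_bp <- sum(nchar(bg))
    for (src in names(pwms)) {
      p <- pwms[[src]]
      fg_hits <- sum(vapply(fg, function(s) count_hits(s, p), 0L))
      bg_hits <- sum(vapply(bg, function(s) count_hits(s, p), 0L))
      d_fg <- 1000 * fg_hits / fg_bp
      d_bg <- 1000 * bg_hits / bg_bp
      rate <- min(1, (bg_hits + 0.5) / bg_bp)
      ratio <- d_fg / (1000 * (bg_hits + 0.5) / bg_bp)
      pv <- if (fg_hits == 0L) 1 else
        binom.test(fg_hits, fg_bp, rate, alternative = "greater")$p.value
      if (ratio >= ratio_min && pv <= p_max) {
        edges[[length(edges) + 1L]] <- data.frame(
          source = src, target = tg, density_fg = d_fg,
          density_bg = d_bg, ratio = ratio, p_value = pv,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(edges) == 0L) {
    return(data.frame(source = character(0), target = character(0),
                      density_fg = numeric(0), density_bg = numeric(0),
                      ratio = numeric(0), p_value = numeric(0)))
  }
  out <- do.call(rbind, edges)
  rownames(out) <- NULL
  out
}

#' Network hierarchy: degrees and the master regulator
#'
#' Counts out- and in-degree per TF (a self-edge contributes to both) and
#' names the TF with the highest out-degree the master regulator,
#' breaking ties lexicographically.
#'
#' @param edges Edge `data.frame` with `source` and `target` columns.
#' @param tfs Optional vector of all TF names (so isolated TFs appear
#'   with degree 0).
#' @return List with `degrees` (`data.frame`: `tf`, `out_degree`,
#'   `in_degree`, `rank`) and `master` (`NA` when there are no edges).
#' @export
hierarchy <- function(edges, tfs = NULL) {
  tfs <- sort(unique(c(tfs, edges$source, edges$target)))
  out_deg <- vapply(tfs, function(t) sum(edges$source == t), 0L)
  in_deg <- vapply(tfs, function(t) sum(edges$target == t), 0L)
  ord <- order(-out_deg, tfs)
  degrees <- data.frame(tf = tfs[ord], out_degree = out_deg[ord],
                        in_degree = in_deg[ord],
                        rank = seq_along(tfs),
                        stringsAsFactors = FALSE)
  master <- if (nrow(edges) == 0L || length(tfs) == 0L) NA_character_
            else degrees$tf[1L]
  list(degrees = degrees, master = master)
}
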