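#' Call allelic imbalance at heterozygous sites
#'
#' For each site an exact binomial test with success probability 0.5 is
#' applied to the human-allele read count out of the site total.  A site
#' is called imbalanced when it has at least `min_total` reads, the
#' human:macaque read ratio exceeds `ratio_thr`, and the binomial p-value
#' is at or below `p_thr`.  Sites below the read minimum are flagged
#' `filtered` and never called.  Replicates should be merged by summing
#' counts before calling.
#'
#' @param counts `data.frame` with columns `reads_h`, `reads_m` (and any
#'   id/class columns, carried through).
#' @param min_total Minimum total reads (default 6).
#' @param ratio_thr Minimum human/macaque read ratio (default 1.3,
#'   strict; `reads_m = 0` counts as infinite ratio).
#' @param p_thr Maximum binomial p-value (default 1e-3).
#' @param alternative `"two.sided"` (default) or `"greater"` for a
#'   one-sided test of human-allele excess.
#' @return The input with added columns `ratio`, `p_value`, `filtered`,
#'   `imbalanced`.
#' @examples
#' call_imbalance(data.frame(reads_h = 20, reads_m = 1))
#' @export
call_imbalance <- function(counts, min_total = 6L, ratio_thr = 1.3,
                           p_thr = 1e-3,
                           alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (any(counts$reads_h < 0 | counts$reads_m < 0)) {
    stop("read counts must be non-negative")
  }
  total <- counts$reads_h + counts$reads_m
  p <- vapply(seq_len(nrow(counts)), function(i) {
    if (total[i] == 0L) return(1)
    binom.test(counts$reads_h[i], total[i], 0.5,
               alternative = alternative)$p.value
  }, 0)
  counts$ratio <- counts$reads_h / counts$reads_m
  counts$p_value <- p
  counts$filtered <- total < min_total
  counts$imbalanced <- !counts$filtered & counts$ratio > ratio_thr &
    p <= p_thr
  counts
}

#' Merge allele counts across replicates
#'
#' Sums the allele-specific counts of each site over replicates before
#' testing; summation is associative so replicate order is irrelevant.
#'
#' @param counts `data.frame` with `site_id`, `reads_h`, `reads_m` (one
#'   row per site and replicate).
#' @return One row per `site_id` with summed counts; other columns keep
#'   the first value seen.
#' @export
merge_replicates <- function(counts) {
  split_rows <- split(seq_len(nrow(counts)), counts$site_id)
  out <- do.call(rbind, lapply(split_rows, function(rows) {
    first <- counts[rows[1L], , drop = FALSE]
    first$reads_h <- sum(counts$reads_h[rows])
    first$reads_m <- sum(counts$reads_m[rows])
    first
  }))
  rownames(out) <- NULL
  out[order(match(out$site_id, counts$site_id)), , drop = FALSE]
}

#' Imbalance fractions by mutation class, with Fisher tests vs background
#'
#' @param calls Output of [call_imbalance()] with a `class` column.
#' @param background Class used as the comparison background (default
#'   `"preserved_background"`).
#' @return `data.frame` per class: `n`, `n_imbalanced`, `fraction`, and
#'   `fisher_p` versus the background class (`NA` for the background
#'   itself).  Empty classes are omitted with a warning.
#' @export
imbalance_enrichment <- function(calls,
                                 background = "preserved_background") {
  if (!background %in% calls$class) {
    stop("background class '", background, "' not present")
  }
  classes <- unique(calls$class)
  empty <- setdiff(classes, unique(calls$class[!is.na(calls$imbalanced)]))
  if (length(empty)) {
    warning("omitting empty class(es): ", paste(empty, collapse = ", "))
    classes <- setdiff(classes, empty)
  }
  bg <- calls[calls$class == background, ]
  out <- do.call(rbind, lapply(classes, function(cl) {
    x <- calls[calls$class == cl, ]
    p <- if (cl == background) NA_real_ else {
      tab <- matrix(c(sum(x$imbalanced), sum(!x$imbalanced),
                      sum(bg$imbalanced), sum(!bg$imbalanced)), 2L)
      fisher.test(tab)$p.value
    }
    data.frame(class = cl, n = nrow(x), n_imbalanced = sum(x$imbalanced),
               fraction = mean(x$imbalanced), fisher_p = p,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
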