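#' Pair orthologous intervals from reciprocal mapping tables
#'
#' Keeps only reciprocal best pairs whose lengths differ by at most
#' `max_length_diff` bp (default 50).  A forward row `A -> B` is
#' reciprocal when the reverse table maps `B` back to `A`.  Duplicate,
#' conflicting mappings of the same interval are dropped with a warning.
#'
#' @param forward `data.frame` with columns `h_chrom,h_start,h_end,
#'   m_chrom,m_start,m_end` (human interval and its macaque image).
#' @param reverse Same columns, mapping macaque intervals back to human.
#' @param max_length_diff Maximum allowed absolute length difference (bp).
#' @return `data.frame` of retained pairs with added `length_diff` and
#'   `reciprocal` columns; non-reciprocal or over-diff rows are absent
#'   (callers treat them as unmapped).
#' @export
pair_orthologs <- function(forward, reverse, max_length_diff = 50L) {
  key <- function(ch, s, e) paste(ch, s, e, sep = ":")
  fkey <- key(forward$h_chrom, forward$h_start, forward$h_end)
  dup <- fkey[duplicated(fkey)]
  if (length(dup)) {
    conflict <- vapply(unique(dup), function(k) {
      rows <- forward[fkey == k, ]
      nrow(unique(rows[, c("m_chrom", "m_start", "m_end")])) > 1L
    }, TRUE)
    if (any(conflict)) {
      warning("dropping ", sum(conflict),
              " human interval(s) with conflicting duplicate mappings")
      forward <- forward[!fkey %in% names(conflict)[conflict], ]
      fkey <- key(forward$h_chrom, forward$h_start, forward$h_end)
    }
    forward <- forward[!duplicated(fkey), ]
    fkey <- key(forward$h_chrom, forward$h_start, forward$h_end)
  }
  # reverse table: which human interval each macaque interval maps back
  # to (reverse rows are macaque source in h_*, human image in m_*)
  back <- setNames(key(reverse$m_chrom, reverse$m_start, reverse$m_end),
                   key(reverse$h_chrom, reverse$h_start, reverse$h_end))
  mkey <- key(forward$m_chrom, forward$m_start, forward$m_end)
  reciprocal <- !is.na(back[mkey]) & back[mkey] == fkey
  len_h <- forward$h_end - forward$h_start
  len_m <- forward$m_end - forward$m_start
  keep <- reciprocal & abs(len_h - len_m) <= max_length_diff
  out <- forward[keep, , drop = FALSE]
  out$length_diff <- abs(len_h - len_m)[keep]
  out$reciprocal <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Extract substitution sites from an aligned sequence pair
#'
#' One site per column where the aligned human and macaque bases differ
#' and neither is a gap; gap columns yield no site (single-nucleotide
#' substitutions only).  When an ancestor sequence is supplied its allele
#' is attached per site.
#'
#' @param human_seq,macaque_seq Aligned sequences of equal length
#'   (gaps as `-`).
#' @param ancestor_seq Optional aligned ancestor sequence.
#' @return `data.frame` with 1-based `position`, `human_allele`,
#'   `macaque_allele`, and `ancestor_allele` (`NA` if no ancestor).
#' @examples
#' extract_mutations("ACGT", "AGGT")
#' @export
extract_mutations <- function(human_seq, macaque_seq,
                              ancestor_seq = NULL) {
  if (nchar(human_seq) != nchar(macaque_seq)) {
    stop("aligned sequences must have equal length")
  }
  h <- strsplit(toupper(human_seq), "")[[1L]]
  m <- strsplit(toupper(macaque_seq), "")[[1L]]
  a <- if (!is.null(ancestor_seq)) {
    if (nchar(ancestor_seq) != nchar(human_seq)) {
      stop("ancestor sequence must match the alignment length")
    }
    strsplit(toupper(ancestor_seq), "")[[1L]]
  } else rep(NA_character_, length(h))
  sub <- which(h != m & h %in% c("A", "C", "G", "T") &
                 m %in% c("A", "C", "G", "T"))
  data.frame(position = sub, human_allele = h[sub],
             macaque_allele = m[sub], ancestor_allele = a[sub],
             stringsAsFactors = FALSE)
}

#' Classify enhancer trios as gained, lost, conserved or ambiguous
#'
#' Implements the trio rule: a de novo gain requires a human peak with a
#' high human score while both the macaque and ancestor sequences score
#' low and macaque lacks a peak; a loss is the mirror image with the
#' ancestor scoring high; conserved requires peaks in both species and
#' high scores in all three genomes.  Everything else is ambiguous.
#' "High" means at or above the threshold, "low" strictly below it.
#' Trios without an ancestor score cannot be polarised and are ambiguous.
#'
#' @param human_peak,macaque_peak Logical vectors: H3K27ac peak presence.
#' @param s_h,s_m,s_a Activity scores in \[0, 1\] for human, macaque and
#'   ancestor (`s_a` may be `NA`).
#' @param threshold A [calibrate_threshold()] result or numeric cutoff.
#' @return Character vector with values `"gained"`, `"lost"`,
#'   `"conserved"`, `"ambiguous"`.
#' @examples
#' classify_status(TRUE, FALSE, 0.8, 0.05, 0.05, 0.197)
#' @export
classify_status <- function(human_peak, macaque_peak, s_h, s_m, s_a,
                            threshold) {
  thr <- thr_value(threshold)
  n <- length(s_h)
  human_peak <- rep_len(human_peak, n)
  macaque_peak <- rep_len(macaque_peak, n)
  s_a <- rep_len(s_a, n)
  status <- rep("ambiguous", n)
  has_anc <- !is.na(s_a)
  gained <- has_anc & human_peak & s_h >= thr & !macaque_peak &
    s_m < thr & s_a < thr
  lost <- has_anc & macaque_peak & s_m >= thr & s_a >= thr &
    !human_peak & s_h < thr
  conserved <- has_anc & human_peak & macaque_peak &
    pmin(s_h, s_m, s_a) >= thr
  status[gained] <- "gained"
  status[lost] <- "lost"
  status[conserved] <- "conserved"
  status
}

#' Is enhancer activity preserved between species?
#'
#' @param h_signal,m_signal Positive H3K27ac signal intensities.
#' @param max_ratio Maximum allowed fold difference (default 1.2,
#'   boundary inclusive).
#' @return Logical: `TRUE` when `max(h/m, m/h) <= max_ratio`.
#' @export
activity_preserved <- function(h_signal, m_signal, max_ratio = 1.2) {
  if (any(h_signal <= 0) || any(m_signal <= 0)) {
    stop("signals must be positive")
  }
  pmax(h_signal / m_signal, m_signal / h_signal) <= max_ratio
}
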