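#' Fourfold-degenerate site positions in a coding sequence
#'
#' Returns the third-codon positions whose codon family is fourfold
#' degenerate under the standard genetic code (any base at the third
#' position encodes the same amino acid).  Reverse-strand CDS input is
#' reverse complemented before codon reading, and positions are reported
#' in the coding orientation.  An internal stop codon triggers a warning
#' but positions are still returned.
#'
#' @param cds_seq Coding sequence, length divisible by 3.
#' @param strand `"+"` or `"-"`.
#' @return Integer vector of 1-based positions (coding orientation).
#' @examples
#' fourfold_sites("GCTAAT")  # GCT (Ala) is fourfold, AAT (Asn) is not
#' @export
fourfold_sites <- function(cds_seq, strand = "+") {
  if (strand == "-") cds_seq <- revcomp(cds_seq)
  cds_seq <- toupper(cds_seq)
  n <- nchar(cds_seq)
  if (n %% 3L != 0L) stop("CDS length must be divisible by 3")
  code <- Biostrings::GENETIC_CODE
  codons <- substring(cds_seq, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- code[codons]
  if (any(aa[-length(aa)] == "*", na.rm = TRUE)) {
    warning("internal stop codon in CDS")
  }
  bases <- c("A", "C", "G", "T")
  fourfold <- vapply(codons, function(cd) {
    if (is.na(code[cd])) return(FALSE)
    fam <- code[paste0(substr(cd, 1L, 2L), bases)]
    length(unique(fam)) == 1L
  }, TRUE)
  unname(which(rep(unname(fourfold), each = 3L) &
                 seq_len(n) %% 3L == 0L))
}

#' Build a McDonald-Kreitman style contingency table
#'
#' Counts fixed (diverged) and polymorphic sites in a foreground class
#' against a background class (by default the mutated fourfold-degenerate
#' sites).
#'
#' @param sites `data.frame` with columns `class` and `fixed` (logical),
#'   as from [simulate_mk_sites()] or a real site table.
#' @param foreground Foreground class name.
#' @param background Background class name (default
#'   `"fourfold_background"`).
#' @return Object of class `mk_table` with fields `Dn`, `Ds`, `Pn`, `Ps`.
#' @export
build_mk_table <- function(sites, foreground,
                           background = "fourfold_background") {
  if (foreground == background) {
    stop("foreground and background classes must differ")
  }
  for (cl in c(foreground, background)) {
    if (!cl %in% sites$class) stop("class not present in sites: ", cl)
  }
  fg <- sites[sites$class == foreground, ]
  bg <- sites[sites$class == background, ]
  structure(list(Dn = sum(fg$fixed), Ds = sum(bg$fixed),
                 Pn = sum(!fg$fixed), Ps = sum(!bg$fixed),
                 foreground = foreground, background = background),
            class = "mk_table")
}

#' @export
print.mk_table <- function(x, ...) {
  cat(sprintf("MK table (%s vs %s): Dn=%d Ds=%d Pn=%d Ps=%d\n",
              x$foreground, x$background, x$Dn, x$Ds, x$Pn, x$Ps))
  invisible(x)
}

#' Direction of selection statistic
#'
#' `DoS = Dn/(Dn+Ds) - Pn/(Pn+Ps)`: positive under adaptive evolution,
#' zero under strict neutrality, negative when slightly deleterious
#' variants segregate.  Both margins must be positive.
#'
#' @param t An [build_mk_table()] result, or a list/vector with elements
#'   `Dn`, `Ds`, `Pn`, `Ps`.
#' @return Numeric value in \[-1, 1\].
#' @examples
#' dos(list(Dn = 15, Ds = 5, Pn = 5, Ps = 15))  # 0.5
#' @export
dos <- function(t) {
  Dn <- t[["Dn"]]; Ds <- t[["Ds"]]; Pn <- t[["Pn"]]; Ps <- t[["Ps"]]
  if (any(c(Dn, Ds, Pn, Ps) < 0)) stop("counts must be non-negative")
  if (Dn + Ds <= 0 || Pn + Ps <= 0) {
    stop("DoS undefined: both the fixed and polymorphic margins must be positive")
  }
  Dn / (Dn + Ds) - Pn / (Pn + Ps)
}

#' Compare derived allele frequency distributions
#'
#' Two-sample rank-sum (Mann-Whitney) comparison.  When the combined
#' sample size is at most 20 the null distribution is enumerated exactly
#' over all group assignments (which handles ties, unlike the classical
#' exact tables); larger samples use the normal approximation with tie
#' correction via [stats::wilcox.test()].
#'
#' @param daf_a,daf_b Numeric vectors of derived allele frequencies.
#' @param alternative Test direction (default `"two.sided"`).
#' @return List with `statistic` (rank sum of the first sample minus its
#'   minimum, i.e. the Mann-Whitney U), `p_value`, `exact`.
#' @export
daf_compare <- function(daf_a, daf_b,
                        alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  na <- length(daf_a); nb <- length(daf_b)
  if (na == 0L || nb == 0L) stop("both samples must be non-empty")
  exact <- na + nb <= 20L
  if (exact) {
    r <- rank(c(daf_a, daf_b))
    w_obs <- sum(r[seq_len(na)])
    combos <- combn(na + nb, na)
    w_perm <- colSums(matrix(r[combos], nrow = na))
    eps <- 1e-9
    p_ge <- mean(w_perm >= w_obs - eps)
    p_le <- mean(w_perm <= w_obs + eps)
    p <- switch(alternative,
                greater = p_ge, less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
    u <- w_obs - na * (na + 1) / 2
    return(list(statistic = u, p_value = p, exact = TRUE))
  }
  wt <- suppressWarnings(
    wilcox.test(daf_a, daf_b, alternative = alternative, exact = FALSE,
                correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       exact = FALSE)
}
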