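#' Read a FASTA file as a named character vector
#'
#' @param path FASTA path.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write named sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Reverse complement of DNA strings
#'
#' Fast `chartr`-based reverse complement over the `ACGTN` alphabet,
#' used in scoring inner loops.
#'
#' @param seqs Character vector of sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seqs) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", seqs)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), "")
}

#' Extract the sequence of an interval from a genome
#'
#' @param genome Named character vector of chromosome sequences (as from
#'   [read_fasta()]).
#' @param interval Single-row interval `data.frame` (0-based half-open);
#'   strand `"-"` returns the reverse complement.
#' @return Uppercase nucleotide string of width `end - start`.
#' @examples
#' extract_sequence(c(chr1 = "ACGTACGT"), genomic_interval("chr1", 2, 6))
#' @export
extract_sequence <- function(genome, interval) {
  stopifnot(nrow(interval) == 1L)
  chrom <- interval$chrom
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  n <- nchar(genome[[chrom]])
  if (interval$start < 0L || interval$end > n) {
    stop(sprintf("interval [%d,%d) out of bounds for %s (length %d)",
                 interval$start, interval$end, chrom, n))
  }
  s <- toupper(substr(genome[[chrom]], interval$start + 1L, interval$end))
  if (identical(interval$strand, "-")) s <- revcomp(s)
  s
}

# One-hot encode a sequence (columns A,C,G,T; N rows are 0.25 each).
# Returns an nchar(seq) x 4 numeric matrix.
one_hot <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  code <- match(chars, c("A", "C", "G", "T"))
  m <- matrix(0, length(chars), 4L)
  known <- !is.na(code)
  if (any(!known)) {
    if (any(chars[!known] != "N")) {
      stop("sequence contains characters outside ACGTN")
    }
    m[!known, ] <- 0.25
  }
  m[cbind(which(known), code[known])] <- 1
  m
}

# Integer codes 1..4 for A,C,G,T; NA for N.  Internal scanning helper.
seq_codes <- function(seq) {
  match(strsplit(toupper(seq), "", fixed = TRUE)[[1L]],
        c("A", "C", "G", "T"))
}

# Random uniform ACGT sequence(s); assumes RNG state is set by the caller.
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, "")
}

# Replace 1-based positions of `seq` with `alleles`.
apply_edits <- function(seq, positions, alleles) {
  if (length(positions) == 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (any(positions < 1L | positions > length(chars))) {
    stop("edit position out of range")
  }
  if (any(chars[positions] == alleles)) {
    stop("edit allele equals the reference allele at position ",
         positions[which(chars[positions] == alleles)[1L]])
  }
  chars[positions] <- alleles
  paste(chars, collapse = "")
}
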