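#' Construct a table of genomic intervals
#'
#' Intervals use 0-based half-open coordinates throughout the package
#' (BED convention): `start` is the first base, `end` is one past the last,
#' so the width is `end - start`.
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector, 0-based inclusive.
#' @param end Integer vector, 0-based exclusive; must satisfy `start < end`.
#' @param strand Strand, one of `"+"`, `"-"`, `"."` (recycled).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`.
#' @examples
#' genomic_interval("chr1", 100, 200)
#' @export
genomic_interval <- function(chrom, start, end, strand = ".") {
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end))) {
    stop("interval coordinates must be integers")
  }
  if (any(start < 0L)) stop("interval start must be >= 0")
  if (any(start >= end)) {
    bad <- which(start >= end)[1L]
    stop(sprintf("interval must satisfy start < end (row %d: %d >= %d)",
                 bad, start[bad], end[bad]))
  }
  if (!all(strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'")
  }
  data.frame(chrom = as.character(chrom), start = start, end = end,
             strand = rep_len(as.character(strand), length(chrom)),
             stringsAsFactors = FALSE)
}

#' Read a BED file of intervals
#'
#' Parses BED3+/BED6 with 0-based half-open coordinates preserved exactly.
#' Malformed lines raise an error naming the offending line number.
#'
#' @param path Path to a tab-separated BED file.
#' @return Interval `data.frame` as from [genomic_interval()]; columns
#'   `name` and `score` are included when present in the file.
#' @seealso [write_bed()] for the byte-exact inverse.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (length(fields) == 0L) {
    return(genomic_interval(character(0), integer(0), integer(0) + 1L)[0, ])
  }
  if (any(ncol < 3L)) {
    stop(sprintf("malformed BED line %d: fewer than 3 tab-separated columns",
                 which(ncol < 3L)[1L]))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  if (any(is.na(start) | is.na(end))) {
    stop(sprintf("malformed BED line %d: non-integer coordinates",
                 which(is.na(start) | is.na(end))[1L]))
  }
  if (any(start >= end)) {
    stop(sprintf("malformed BED line %d: start >= end",
                 which(start >= end)[1L]))
  }
  out <- data.frame(chrom = chrom, start = start, end = end,
                    strand = ".", stringsAsFactors = FALSE)
  if (all(ncol >= 4L)) out$name <- vapply(fields, `[[`, "", 4L)
  if (all(ncol >= 5L)) out$score <- vapply(fields, `[[`, "", 5L)
  if (all(ncol >= 6L)) {
    strand <- vapply(fields, `[[`, "", 6L)
    if (!all(strand %in% c("+", "-", "."))) {
      stop(sprintf("malformed BED line %d: invalid strand",
                   which(!strand %in% c("+", "-", "."))[1L]))
    }
    out$strand <- strand
  }
  out
}

#' Write intervals as BED
#'
#' @param x Interval `data.frame` (columns `chrom`, `start`, `end`, and
#'   optionally `name`, `score`, `strand`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  cols <- c("chrom", "start", "end")
  extra <- intersect(c("name", "score", "strand"), names(x))
  # BED column order is positional: emit name/score only up to the first gap
  keep <- character(0)
  for (col in c("name", "score", "strand")) {
    if (col %in% extra) keep <- c(keep, col) else break
  }
  out <- x[, c(cols, keep), drop = FALSE]
  lines <- do.call(paste, c(unname(as.list(out)), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Expects a tab-separated file with a header naming at least
#' `gene_id`, `chrom`, `tss`, `strand`; `tss` is a 0-based position.
#'
#' @param path Path to the TSV file.
#' @return `data.frame` with those columns.
#' @export
read_gene_table <- function(path) {
  g <- read.table(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "tss", "strand")
  miss <- setdiff(need, names(g))
  if (length(miss)) stop("gene table missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(g$tss < 0)) stop("tss must be >= 0")
  g
}

#' Build fixed-width enhancers from peak intervals
#'
#' Each peak is replaced by the 1-kb window centred on the peak centre
#' (`floor((start + end) / 2)`), and any window overlapping a promoter
#' (the interval `[tss - promoter_pad, tss + promoter_pad]` of any supplied
#' TSS, including alternative TSSs) is removed.  Windows that would run off
#' a chromosome end are clamped to `[0, chrom_len]` and flagged
#' `clamped = TRUE`; by default they are dropped so that every retained
#' enhancer is exactly `2 * half_width` bp wide.
#'
#' @param peaks Interval `data.frame` of peaks; an optional `signal` column
#'   (non-negative peak intensity) is carried through.
#' @param genes Gene annotation `data.frame` (`gene_id`, `chrom`, `tss`),
#'   or `NULL` to skip promoter filtering.
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param half_width Half window width in bp (default 500, i.e. 1-kb
#'   enhancers).
#' @param promoter_pad Promoter half width around each TSS in bp
#'   (default 1000).
#' @param drop_clamped Drop chromosome-edge enhancers (default `TRUE`).
#' @return `data.frame` with columns `chrom`, `start`, `end`, `signal`,
#'   `clamped`, `src_start`, `src_end`.
#' @examples
#' peaks <- genomic_interval("chr1", 1300, 1700)
#' make_enhancers(peaks, genes = NULL, chrom_lengths = c(chr1 = 100000))
#' @export
make_enhancers <- function(peaks, genes, chrom_lengths,
                           half_width = 500L, promoter_pad = 1000L,
                           drop_clamped = TRUE) {
  if (!all(peaks$chrom %in% names(chrom_lengths))) {
    stop("peaks on chromosomes without a known length: ",
         paste(unique(setdiff(peaks$chrom, names(chrom_lengths))),
               collapse = ", "))
  }
  centre <- (peaks$start + peaks$end) %/% 2L
  start <- centre - as.integer(half_width)
  end <- centre + as.integer(half_width)
  len <- unname(chrom_lengths[peaks$chrom])
  clamped <- start < 0L | end > len
  start <- pmax(start, 0L)
  end <- pmin(end, len)
  signal <- if ("signal" %in% names(peaks)) as.numeric(peaks$signal) else
    rep(NA_real_, nrow(peaks))
  if (any(!is.na(signal) & signal < 0)) stop("signal must be >= 0")
  enh <- data.frame(chrom = peaks$chrom, start = start, end = end,
                    signal = signal, clamped = clamped,
                    src_start = peaks$start, src_end = peaks$end,
                    stringsAsFactors = FALSE)
  if (!is.null(genes) && nrow(enh) > 0L && nrow(genes) > 0L) {
    pad <- as.integer(promoter_pad)
    # promoters are closed [tss - pad, tss + pad]; half-open end is tss+pad+1
    keep <- vapply(seq_len(nrow(enh)), function(i) {
      g <- genes[genes$chrom == enh$chrom[i], , drop = FALSE]
      if (nrow(g) == 0L) return(TRUE)
      !any(enh$start[i] < g$tss + pad + 1L & g$tss - pad < enh$end[i])
    }, logical(1))
    enh <- enh[keep, , drop = FALSE]
  }
  if (drop_clamped) enh <- enh[!enh$clamped, , drop = FALSE]
  rownames(enh) <- NULL
  enh
}
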