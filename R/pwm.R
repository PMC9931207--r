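#' Construct a position weight matrix (PWM)
#'
#' The matrix holds per-position base probabilities with columns
#' A, C, G, T; rows must sum to one.  Log-odds scores are taken base 2
#' against the background after smoothing every cell with a pseudocount
#' of 1e-3 (renormalised), so zero probabilities stay finite.
#'
#' @param name Motif name.
#' @param matrix Numeric `width x 4` matrix of base probabilities
#'   (columns A, C, G, T).
#' @param background Background base frequencies (default uniform).
#' @param threshold Log-odds hit cutoff; usually set by
#'   [calibrate_pwm_threshold()].
#' @return Object of class `pwm`.
#' @export
pwm <- function(name, matrix, background = rep(0.25, 4), threshold = NA_real_) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 4L) stop("PWM matrix must have 4 columns (A,C,G,T)")
  if (nrow(matrix) < 4L) stop("PWM width must be >= 4")
  if (any(abs(rowSums(matrix) - 1) > 1e-9)) {
    stop("PWM rows must sum to 1")
  }
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-9) {
    stop("background must be 4 frequencies summing to 1")
  }
  colnames(matrix) <- c("A", "C", "G", "T")
  structure(list(name = name, matrix = matrix,
                 background = as.numeric(background),
                 threshold = threshold),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s': width %d, consensus %s, threshold %s\n",
              x$name, nrow(x$matrix), pwm_consensus(x),
              if (is.na(x$threshold)) "uncalibrated"
              else format(x$threshold, digits = 4)))
  invisible(x)
}

#' Consensus sequence of a PWM
#'
#' @param x A [pwm()] object.
#' @return Character string of per-position most probable bases.
#' @export
pwm_consensus <- function(x) {
  paste(c("A", "C", "G", "T")[max.col(x$matrix, ties.method = "first")],
        collapse = "")
}

# Smoothed base-2 log-odds matrix (width x 4).
pwm_logodds <- function(x, pseudocount = 1e-3) {
  p <- (x$matrix + pseudocount) / (1 + 4 * pseudocount)
  log2(sweep(p, 2L, x$background, "/"))
}

# Maximum attainable log-odds score.
pwm_max_score <- function(x) sum(apply(pwm_logodds(x), 1L, max))

# Score every window of `codes` (integer codes, NA for N) against a
# log-odds matrix.  Returns numeric vector of length len - w + 1 (or
# length 0 when the sequence is shorter than the motif).
scan_scores <- function(codes, lo) {
  w <- nrow(lo)
  n <- length(codes)
  if (n < w) return(numeric(0))
  # N positions contribute the background-expected log-odds of that row
  nvals <- rowSums(sweep(lo, 2L, c(0.25, 0.25, 0.25, 0.25), "*"))
  out <- numeric(n - w + 1L)
  for (j in seq_len(w)) {
    cj <- codes[j:(j + n - w)]
    v <- lo[j, ][cj]
    v[is.na(cj)] <- nvals[j]
    out <- out + v
  }
  out
}

#' Scan a sequence for PWM hits
#'
#' Both strands are scanned; a hit is any window whose base-2 log-odds
#' score reaches the threshold.  Offsets are 0-based positions of the
#' window start on the forward strand (for `-` strand hits, the offset of
#' the window whose reverse complement matched).
#'
#' @param seq Nucleotide string.
#' @param x A [pwm()] object.
#' @param threshold Log-odds cutoff; defaults to the PWM's calibrated
#'   threshold.
#' @param both_strands Scan the reverse strand too (default `TRUE`).
#' @return `data.frame` with columns `offset`, `strand`, `score`; zero rows
#'   when the sequence is shorter than the motif or nothing passes.
#' @export
scan_pwm <- function(seq, x, threshold = x$threshold, both_strands = TRUE) {
  if (is.na(threshold)) {
    stop("PWM '", x$name,
         "' has no threshold; run calibrate_pwm_threshold() first")
  }
  lo <- pwm_logodds(x)
  w <- nrow(lo)
  codes <- seq_codes(seq)
  fwd <- scan_scores(codes, lo)
  hits <- which(fwd >= threshold)
  out <- data.frame(offset = hits - 1L,
                    strand = rep("+", length(hits)),
                    score = fwd[hits], stringsAsFactors = FALSE)
  if (both_strands) {
    # reverse-complement the log-odds matrix instead of the sequence:
    # score of the RC motif at forward offset i equals the motif score of
    # the RC sequence window
    lo_rc <- lo[rev(seq_len(w)), c(4L, 3L, 2L, 1L), drop = FALSE]
    rev_ <- scan_scores(codes, lo_rc)
    hits2 <- which(rev_ >= threshold)
    out <- rbind(out, data.frame(offset = hits2 - 1L,
                                 strand = rep("-", length(hits2)),
                                 score = rev_[hits2],
                                 stringsAsFactors = FALSE))
  }
  out[order(out$offset, out$strand), , drop = FALSE]
}

#' Calibrate a PWM hit threshold to a false-positive budget
#'
#' Scans random background sequences (both strands) and returns the
#' smallest observed log-odds score such that the hit rate does not exceed
#' `max_fp` hits per 10 kb of sequence.  If even the maximal observed score
#' is too permissive (e.g. a degenerate uniform motif), a threshold just
#' above the maximum score is returned so that nothing passes.
#'
#' @param x A [pwm()] object.
#' @param seqs Character vector of background sequences totalling at least
#'   100 kb.
#' @param max_fp Allowed false positives per 10 kb (default 5).
#' @return The calibrated threshold (numeric); assign it into the PWM with
#'   `x$threshold <- ...` or use [calibrate_pwms()].
#' @export
calibrate_pwm_threshold <- function(x, seqs, max_fp = 5) {
  total_bp <- sum(nchar(seqs))
  if (total_bp < 1e5) {
    stop("calibration sequences must total at least 100 kb (got ",
         total_bp, " bp)")
  }
  lo <- pwm_logodds(x)
  w <- nrow(lo)
  if (any(nchar(seqs) < w)) stop("motif wider than a calibration sequence")
  lo_rc <- lo[rev(seq_len(w)), c(4L, 3L, 2L, 1L), drop = FALSE]
  scores <- unlist(lapply(seqs, function(s) {
    codes <- seq_codes(s)
    c(scan_scores(codes, lo), scan_scores(codes, lo_rc))
  }))
  allowed <- max_fp * total_bp / 1e4
  s_sorted <- sort(scores)
  cand <- unique(s_sorted)
  # windows scoring >= each candidate: exact float match against the sort
  n_ge <- length(scores) - match(cand, s_sorted) + 1L
  ok <- which(n_ge <= allowed)
  if (length(ok) == 0L) {
    return(max(scores) + 1e-9)
  }
  cand[ok[1L]]
}

#' Calibrate thresholds for a list of PWMs
#'
#' @param pwms List of [pwm()] objects.
#' @param seqs Background sequences (>= 100 kb total).
#' @param max_fp Allowed false positives per 10 kb.
#' @return The list with `threshold` fields set.
#' @export
calibrate_pwms <- function(pwms, seqs, max_fp = 5) {
  lapply(pwms, function(p) {
    p$threshold <- calibrate_pwm_threshold(p, seqs, max_fp)
    p
  })
}

#' Read motifs from a minimal MEME-format file
#'
#' Supports the MEME minimal format: a `Background letter frequencies`
#' line, and per motif a `MOTIF <name>` line, a
#' `letter-probability matrix:` header and `w` rows of four probabilities.
#'
#' @param path Path to the motif file.
#' @return Named list of [pwm()] objects (thresholds unset).
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i)) {
    toks <- strsplit(trimws(lines[bg_i[1L] + 1L]), "\\s+")[[1L]]
    freq <- suppressWarnings(as.numeric(toks))
    bg <- freq[!is.na(freq)]
    if (length(bg) != 4L) bg <- rep(0.25, 4)
  }
  motif_i <- grep("^MOTIF", lines)
  out <- list()
  for (i in motif_i) {
    name <- strsplit(trimws(lines[i]), "\\s+")[[1L]][2L]
    hdr <- i + which(grepl("letter-probability matrix",
                           lines[(i + 1):length(lines)]))[1L]
    if (is.na(hdr)) stop("motif ", name, ": no letter-probability matrix")
    w <- suppressWarnings(as.integer(
      sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr])))
    rows <- lines[(hdr + 1):(hdr + w)]
    mat <- do.call(rbind, lapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1L]])
    }))
    mat <- mat / rowSums(mat)
    out[[name]] <- pwm(name, mat, background = bg)
  }
  out
}

#' Write motifs in minimal MEME format
#'
#' @param pwms Named list of [pwm()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", c("A", "C", "G", "T"),
                             pwms[[1L]]$background), collapse = " "),
               ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$name), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      nrow(p$matrix)), con)
    writeLines(apply(p$matrix, 1L, function(r) {
      paste(sprintf("%.6f", r), collapse = " ")
    }), con)
    writeLines("", con)
  }
  invisible(path)
}
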