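# Round half away from zero, the convention used for printed percentages.
round_half_away <- function(x, digits = 0L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Report a count as a printed percentage
#'
#' @param numerator,denominator Non-negative counts with
#'   `numerator <= denominator`, `denominator > 0`.
#' @param decimals Decimal places of the printed percent (rounded half
#'   away from zero).
#' @return Object of class `fraction_report` with `numerator`,
#'   `denominator`, `percent`.
#' @examples
#' fraction(828, 4066, 1)  # 20.4
#' @export
fraction <- function(numerator, denominator, decimals = 1L) {
  if (denominator <= 0) stop("denominator must be positive")
  if (numerator < 0 || numerator > denominator) {
    stop("numerator must lie in [0, denominator]")
  }
  structure(list(numerator = numerator, denominator = denominator,
                 percent = round_half_away(100 * numerator / denominator,
                                           decimals)),
            class = "fraction_report")
}

#' @export
print.fraction_report <- function(x, ...) {
  cat(sprintf("%d / %d = %s%%\n", x$numerator, x$denominator,
              format(x$percent)))
  invisible(x)
}

#' Subsampling ("90% bootstrap") uncertainty of a fraction
#'
#' Each replicate subsamples `floor(keep_frac * n)` items without
#' replacement and records the fraction of `TRUE` values; the median and
#' standard deviation over replicates are reported.  This matches the
#' stated "90% bootstrapping" resampling scheme (subsampling without
#' replacement rather than the classical with-replacement bootstrap);
#' set `replace = TRUE` for the classical variant.
#'
#' @param items Logical vector (length at least 10).
#' @param keep_frac Fraction retained per replicate, in (0, 1\].
#' @param reps Number of replicates (default 50).
#' @param seed RNG seed.
#' @param replace Sample with replacement instead.
#' @return List with `median`, `sd`, and the replicate `fractions`.
#' @export
bootstrap_fraction <- function(items, keep_frac = 0.9, reps = 50L,
                               seed = 1L, replace = FALSE) {
  if (keep_frac <= 0 || keep_frac > 1) {
    stop("keep_frac must be in (0, 1]")
  }
  if (length(items) < 10L) stop("need at least 10 items")
  set.seed(seed)
  k <- floor(keep_frac * length(items))
  fr <- vapply(seq_len(reps), function(i) {
    mean(items[sample.int(length(items), k, replace = replace)])
  }, 0)
  list(median = median(fr), sd = sd(fr), fractions = fr)
}

#' Fisher's exact test on a 2x2 table
#'
#' Conditional hypergeometric two-sided p-value (tables with probability
#' at most that observed) and the sample odds ratio `ad/bc`; when any
#' cell is zero the odds ratio uses a 0.5 pseudocount per cell and is
#' flagged `adjusted`.
#'
#' @param a,b,c,d Non-negative integer cells, row-wise
#'   (`a b` / `c d`).
#' @return List with `odds_ratio`, `p_value`, `adjusted`.
#' @examples
#' fisher_2x2(5, 5, 5, 5)
#' @export
fisher_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != floor(cells))) {
    stop("cells must be non-negative integers")
  }
  if (sum(cells) == 0) stop("all-zero table")
  adjusted <- any(cells == 0)
  or <- if (adjusted) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else (a * d) / (b * c)
  p <- fisher.test(matrix(cells, 2L, byrow = TRUE))$p.value
  list(odds_ratio = or, p_value = p, adjusted = adjusted)
}

#' Write a reproducibility manifest
#'
#' Records the package version, seeds, configuration and input-file
#' checksums of an analysis run as JSON, sufficient to reproduce outputs.
#'
#' @param path Output JSON path.
#' @param config List of configuration values.
#' @param seeds Named integer vector of seeds used.
#' @param inputs Character vector of input file paths to checksum.
#' @return The manifest list, invisibly.
#' @export
run_manifest <- function(path, config = list(), seeds = c(seed = 1L),
                         inputs = character(0)) {
  manifest <- list(
    package = "enhgain",
    version = as.character(utils::packageVersion("enhgain")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seeds = as.list(seeds),
    config = config,
    inputs = if (length(inputs)) {
      data.frame(path = inputs, md5 = unname(tools::md5sum(inputs)),
                 stringsAsFactors = FALSE)
    } else NULL)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
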