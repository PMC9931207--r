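#' Simulation configuration
#'
#' Bundles the knobs of the synthetic-data generator.  Defaults encode the
#' study conditions the pipeline assumes: 1-kb enhancers carrying on
#' average 50 human-macaque substitutions, binomially sampled allele reads
#' at 30x depth, and a 4:1 allelic imbalance for truly imbalanced sites.
#'
#' @param seed Integer seed; a fixed seed makes every generator output
#'   byte-identical.
#' @param n_enhancers Number of enhancer trios to simulate.
#' @param enhancer_len Enhancer length in bp (default 1000).
#' @param n_background Number of background sequences.
#' @param substitution_rate Mean human-macaque substitutions per kb
#'   (default 50).
#' @param activator_pwms,repressor_pwms Lists of [pwm()] objects with
#'   thresholds set; defaults come from [example_pwms()].
#' @param planted_gain_fraction Fraction of trios planted as gains when a
#'   status mix is drawn.
#' @param read_depth Reads per heterozygous site.
#' @param imbalance_ratio Human:macaque allele read ratio at imbalanced
#'   sites (>= 1).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_enhancers = 200L, enhancer_len = 1000L,
                       n_background = 1000L, substitution_rate = 50,
                       activator_pwms = example_pwms("activator"),
                       repressor_pwms = example_pwms("repressor"),
                       planted_gain_fraction = 0.4,
                       read_depth = 30L, imbalance_ratio = 4) {
  if (substitution_rate < 0) stop("substitution_rate must be >= 0")
  if (planted_gain_fraction < 0 || planted_gain_fraction > 1) {
    stop("planted_gain_fraction must be in [0, 1]")
  }
  if (imbalance_ratio < 1) stop("imbalance_ratio must be >= 1")
  structure(list(seed = as.integer(seed),
                 n_enhancers = as.integer(n_enhancers),
                 enhancer_len = as.integer(enhancer_len),
                 n_background = as.integer(n_background),
                 substitution_rate = substitution_rate,
                 activator_pwms = activator_pwms,
                 repressor_pwms = repressor_pwms,
                 planted_gain_fraction = planted_gain_fraction,
                 read_depth = as.integer(read_depth),
                 imbalance_ratio = imbalance_ratio),
            class = "sim_config")
}

#' Built-in example motifs
#'
#' Sharp (94% dominant base) non-palindromic 8-mers used by the generator
#' to plant activator and repressor binding sites.  Thresholds are preset
#' at 80% of the maximal log-odds score, which a consensus match clears
#' and any single-base mismatch does not — the property that makes planted
#' essential mutations exactly recoverable.
#'
#' @param role `"activator"` or `"repressor"`.
#' @return Named list of calibrated [pwm()] objects.
#' @export
example_pwms <- function(role = c("activator", "repressor")) {
  role <- match.arg(role)
  consensus <- switch(role,
                      activator = c("TGACCTAG", "CACGCTTA"),
                      repressor = c("AGGTCATC"))
  names(consensus) <- switch(role,
                             activator = c("ACT1", "ACT2"),
                             repressor = c("REP1"))
  lapply(setNames(names(consensus), names(consensus)), function(nm) {
    chars <- strsplit(consensus[[nm]], "")[[1L]]
    m <- matrix(0.02, length(chars), 4L)
    m[cbind(seq_along(chars), match(chars, c("A", "C", "G", "T")))] <- 0.94
    p <- pwm(nm, m)
    p$threshold <- 0.8 * pwm_max_score(p)
    p
  })
}

# Most informative PWM position (lowest entropy row; first on ties) and
# the least likely base there (alphabetical on ties).
pwm_key_position <- function(p) {
  ent <- apply(p$matrix, 1L, function(r) -sum(r * log(pmax(r, 1e-12))))
  j <- which.min(ent)
  list(pos = j, broken = c("A", "C", "G", "T")[which.min(p$matrix[j, ])],
       consensus = c("A", "C", "G", "T")[which.max(p$matrix[j, ])])
}

count_hits <- function(seq, p) nrow(scan_pwm(seq, p))

#' Simulate one ancestor/human/macaque enhancer trio with ground truth
#'
#' For status `"gained"`, the ancestor and macaque sequences carry a
#' planted activator motif broken at its most informative position, and
#' the human sequence restores the consensus there via a single designated
#' essential substitution; motif scans therefore find a hit in human and
#' none in macaque or the ancestor.  `"lost"` mirrors this (motif intact
#' in ancestor and macaque, destroyed in human), `"conserved"` plants an
#' intact motif in all three, and `"neutral"` plants nothing.  All other
#' human-macaque substitutions are placed outside the motif footprint,
#' with total count Poisson-distributed at the configured per-kb rate.
#'
#' @param config A [sim_config()].
#' @param status One of `"gained"`, `"lost"`, `"conserved"`, `"neutral"`.
#' @param seed Optional seed; when `NULL` the current RNG state is used
#'   (so a set can be generated from one stream).
#' @return Object of class `trio_truth`: sequences, a `mutations` table
#'   (1-based `position`, `human_allele`, `macaque_allele`,
#'   `ancestor_allele`, `lineage`), `essential_positions`, and `status`.
#' @export
simulate_trio <- function(config, status = c("gained", "lost", "conserved",
                                             "neutral"),
                          seed = NULL) {
  status <- match.arg(status)
  if (!is.null(seed)) set.seed(seed)
  len <- config$enhancer_len
  pwm <- config$activator_pwms[[1L]]
  w <- nrow(pwm$matrix)
  if (w > len) stop("motif is longer than the enhancer sequence")
  bases <- c("A", "C", "G", "T")
  key <- pwm_key_position(pwm)
  cons <- strsplit(pwm_consensus(pwm), "")[[1L]]
  for (attempt in seq_len(100L)) {
    anc <- strsplit(random_dna(1L, len), "")[[1L]]
    m0 <- if (status == "neutral") NA_integer_ else
      sample(seq(5L, len - w - 4L), 1L)
    essential_pos <- integer(0)
    if (status != "neutral") {
      motif <- cons
      if (status %in% c("gained")) motif[key$pos] <- key$broken
      anc[m0:(m0 + w - 1L)] <- motif
    }
    human <- anc
    macaque <- anc
    # background human-macaque substitutions outside the motif footprint
    k <- rpois(1L, config$substitution_rate * len / 1000)
    if (status %in% c("gained", "lost")) k <- max(k, 1L)
    n_bg <- if (status %in% c("gained", "lost")) k - 1L else k
    avoid <- if (is.na(m0)) integer(0) else m0:(m0 + w - 1L)
    free <- setdiff(seq_len(len), avoid)
    pos_bg <- sort(sample(free, min(n_bg, length(free))))
    lineage <- sample(c("human", "macaque"), length(pos_bg),
                      replace = TRUE)
    for (idx in seq_along(pos_bg)) {
      pos <- pos_bg[idx]
      new <- sample(setdiff(bases, anc[pos]), 1L)
      if (lineage[idx] == "human") human[pos] <- new else
        macaque[pos] <- new
    }
    if (status == "gained") {
      ep <- m0 + key$pos - 1L
      human[ep] <- key$consensus
      essential_pos <- ep
    } else if (status == "lost") {
      ep <- m0 + key$pos - 1L
      human[ep] <- key$broken
      essential_pos <- ep
    }
    hs <- paste(human, collapse = "")
    ms <- paste(macaque, collapse = "")
    as <- paste(anc, collapse = "")
    hits <- c(h = count_hits(hs, pwm), m = count_hits(ms, pwm),
              a = count_hits(as, pwm))
    # "no activator match" must hold against every configured activator,
    # not just the planted one, so downstream scorers see a clean trio
    any_hits <- function(s) {
      sum(vapply(config$activator_pwms, function(p) count_hits(s, p), 0L))
    }
    ok <- switch(status,
                 gained = hits["h"] >= 1L && any_hits(ms) == 0L &&
                   any_hits(as) == 0L,
                 lost = any_hits(hs) == 0L && hits["m"] >= 1L &&
                   hits["a"] >= 1L,
                 conserved = all(hits >= 1L),
                 neutral = any_hits(hs) == 0L && any_hits(ms) == 0L &&
                   any_hits(as) == 0L)
    if (!ok) next
    diff_pos <- which(human != macaque)
    muts <- data.frame(
      position = diff_pos,
      human_allele = human[diff_pos],
      macaque_allele = macaque[diff_pos],
      ancestor_allele = anc[diff_pos],
      lineage = ifelse(human[diff_pos] != anc[diff_pos], "human",
                       "macaque"),
      stringsAsFactors = FALSE)
    return(structure(list(ancestor_seq = as, human_seq = hs,
                          macaque_seq = ms, mutations = muts,
                          essential_positions = essential_pos,
                          status = status, motif = pwm$name,
                          motif_offset = m0),
                     class = "trio_truth"))
  }
  stop("failed to construct a valid trio in 100 attempts; ",
       "check PWM thresholds and sequence length")
}

#' @export
print.trio_truth <- function(x, ...) {
  cat(sprintf(
    "Synthetic trio (%s): %d bp, %d human-macaque substitutions, %d essential\n",
    x$status, nchar(x$human_seq), nrow(x$mutations),
    length(x$essential_positions)))
  invisible(x)
}

#' Simulate a set of trios from one seeded stream
#'
#' @param config A [sim_config()].
#' @param statuses Character vector of intended statuses, one per trio.
#' @param seed Seed for the whole set (default `config$seed`).
#' @return List of [simulate_trio()] results.
#' @export
simulate_trio_set <- function(config, statuses, seed = config$seed) {
  set.seed(seed)
  lapply(statuses, function(s) simulate_trio(config, s, seed = NULL))
}

#' Simulate a labelled training set of enhancer and background sequences
#'
#' Positives are random sequences with one or two planted intact motif
#' instances; negatives are random sequences rejected until they contain
#' no motif hit, making the two classes separable by construction.
#' Chromosome labels are drawn uniformly so the chromosome-based
#' train/validation/test split is well populated.
#'
#' @param n_pos,n_neg Class sizes.
#' @param len Sequence length in bp.
#' @param pwms Calibrated motif list (default [example_pwms()]).
#' @param seed RNG seed.
#' @param chroms Chromosome labels to draw from.
#' @return `data.frame` with columns `id`, `chrom`, `label`, `seq`.
#' @export
simulate_training_set <- function(n_pos, n_neg, len = 200L,
                                  pwms = example_pwms("activator"),
                                  seed = 1L,
                                  chroms = paste0("chr", 1:22)) {
  set.seed(seed)
  w <- max(vapply(pwms, function(p) nrow(p$matrix), 0L))
  seqs <- character(n_pos + n_neg)
  for (i in seq_len(n_pos)) {
    s <- strsplit(random_dna(1L, len), "")[[1L]]
    n_plant <- sample(1:2, 1L)
    starts <- sample(seq(1L, len - w + 1L, by = w + 2L), n_plant)
    for (st in starts) {
      p <- pwms[[sample(length(pwms), 1L)]]
      s[st:(st + nrow(p$matrix) - 1L)] <-
        strsplit(pwm_consensus(p), "")[[1L]]
    }
    seqs[i] <- paste(s, collapse = "")
  }
  for (i in seq_len(n_neg)) {
    repeat {
      s <- random_dna(1L, len)
      if (all(vapply(pwms, function(p) count_hits(s, p), 0L) == 0L)) break
    }
    seqs[n_pos + i] <- s
  }
  data.frame(id = sprintf("seq%05d", seq_len(n_pos + n_neg)),
             chrom = sample(chroms, n_pos + n_neg, replace = TRUE),
             label = rep(c(1L, 0L), c(n_pos, n_neg)),
             seq = seqs, stringsAsFactors = FALSE)
}

#' Simulate allele-specific read counts at heterozygous sites
#'
#' Each site receives `read_depth` reads; the human-allele count is drawn
#' from `Binomial(depth, r / (1 + r))` where `r` is the configured
#' imbalance ratio for truly imbalanced sites and 1 for balanced sites.
#'
#' @param config A [sim_config()].
#' @param n_sites Number of sites.
#' @param imbalanced Logical vector (recycled) marking truly imbalanced
#'   sites.
#' @param seed RNG seed (default `config$seed`).
#' @return `data.frame` with `site_id`, `truly_imbalanced`, `reads_h`,
#'   `reads_m`.
#' @export
simulate_het_reads <- function(config, n_sites, imbalanced = FALSE,
                               seed = config$seed) {
  set.seed(seed)
  if (config$read_depth < 0L) stop("read_depth must be >= 0")
  imb <- rep_len(as.logical(imbalanced), n_sites)
  r <- ifelse(imb, config$imbalance_ratio, 1)
  reads_h <- rbinom(n_sites, config$read_depth, r / (1 + r))
  data.frame(site_id = sprintf("site%05d", seq_len(n_sites)),
             truly_imbalanced = imb,
             reads_h = reads_h,
             reads_m = config$read_depth - reads_h,
             stringsAsFactors = FALSE)
}

#' Simulate fixed/polymorphic site tables for selection tests
#'
#' Per site class, each site is fixed with the class's configured
#' probability; polymorphic sites receive a derived allele frequency drawn
#' from a Beta distribution (default Beta(1, 3), skewed towards rare
#' derived alleles as under neutrality).
#'
#' @param n_per_class Named integer vector of site counts per class.
#' @param fixed_fraction Named numeric vector in \[0, 1\], same names.
#' @param daf_shape Two Beta shape parameters for polymorphic DAFs.
#' @param seed RNG seed.
#' @return `data.frame` with `site_id`, `class`, `fixed`, `daf` (`NA` for
#'   fixed sites).
#' @export
simulate_mk_sites <- function(n_per_class, fixed_fraction,
                              daf_shape = c(1, 3), seed = 1L) {
  if (any(fixed_fraction < 0 | fixed_fraction > 1)) {
    stop("fixed_fraction values must lie in [0, 1]")
  }
  if (!all(names(n_per_class) %in% names(fixed_fraction))) {
    stop("fixed_fraction must name every class in n_per_class")
  }
  set.seed(seed)
  out <- lapply(names(n_per_class), function(cl) {
    n <- n_per_class[[cl]]
    if (n == 0L) return(NULL)
    fixed <- runif(n) < fixed_fraction[[cl]]
    daf <- ifelse(fixed, NA_real_, rbeta(n, daf_shape[1], daf_shape[2]))
    data.frame(site_id = paste0(cl, "_", seq_len(n)), class = cl,
               fixed = fixed, daf = daf, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(site_id = character(0), class = character(0),
                      fixed = logical(0), daf = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Simulate a TF expression matrix consistent with a regulatory network
#'
#' Each TF has an independent latent activity; a regulated TF's expression
#' is the sum of its regulators' latents plus Gaussian noise, so linked
#' pairs are positively correlated and unlinked pairs are independent.
#'
#' @param edges `data.frame` with columns `source`, `target`.
#' @param tfs Character vector of all TF names.
#' @param n_samples Number of samples (columns); fewer than 3 triggers a
#'   warning because correlations are then uninformative.
#' @param noise_sd Noise standard deviation.
#' @param seed RNG seed.
#' @return Numeric matrix, TFs in rows, samples in columns.
#' @export
simulate_expression <- function(edges, tfs, n_samples = 50L,
                                noise_sd = 0.3, seed = 1L) {
  if (n_samples < 3L) {
    warning("fewer than 3 samples: correlations will be uninformative")
  }
  set.seed(seed)
  latent <- matrix(rnorm(length(tfs) * n_samples), length(tfs), n_samples,
                   dimnames = list(tfs, NULL))
  expr <- latent
  for (tf in tfs) {
    reg <- unique(edges$source[edges$target == tf])
    reg <- intersect(reg, tfs)
    if (length(reg)) {
      expr[tf, ] <- colSums(latent[reg, , drop = FALSE]) +
        noise_sd * rnorm(n_samples)
    } else {
      expr[tf, ] <- latent[tf, ] + noise_sd * rnorm(n_samples)
    }
  }
  expr
}

#' Simulate log-normal peak signal intensities
#'
#' Integrated H3K27ac-like intensities with multiplicative (log-normal)
#' noise, the stand-in noise model used for synthetic enhancer signal.
#'
#' @param n Number of values.
#' @param meanlog,sdlog Log-normal parameters.
#' @param seed RNG seed, or `NULL` to use the current stream.
#' @return Numeric vector of positive signals.
#' @export
simulate_signal <- function(n, meanlog = 3, sdlog = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  exp(rnorm(n, meanlog, sdlog))
}
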