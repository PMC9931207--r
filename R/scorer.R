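#' Configure the convolutional sequence-to-activity scorer
#'
#' The full-scale reference architecture has five convolution layers with
#' 320, 320, 240, 240 and 480 kernels followed by a 180-unit dense layer on
#' 1-kb input.  The default here is a deliberately small two-layer network
#' on 200-bp input, sized for desk-scale training; use
#' [reference_config()] for the full-scale layer plan.
#'
#' @param input_len Input sequence length in bp.
#' @param conv_kernels Integer vector of kernel counts per conv layer.
#' @param kernel_widths Integer vector of kernel widths (bp), same length.
#' @param pool_sizes Integer vector of non-overlapping max-pool sizes,
#'   same length.
#' @param dense_units Units in the fully connected layer.
#' @param output_units Output units (1 = sigmoid).
#' @return Object of class `enh_model_config`.
#' @export
model_config <- function(input_len = 200L,
                         conv_kernels = c(32L, 32L),
                         kernel_widths = c(11L, 7L),
                         pool_sizes = c(4L, 41L),
                         dense_units = 32L,
                         output_units = 1L) {
  if (length(conv_kernels) != length(kernel_widths) ||
      length(conv_kernels) != length(pool_sizes)) {
    stop("conv_kernels, kernel_widths and pool_sizes must have equal length")
  }
  if (any(c(conv_kernels, kernel_widths, pool_sizes,
            dense_units, output_units, input_len) < 1L)) {
    stop("all architecture counts must be positive")
  }
  cfg <- structure(list(input_len = as.integer(input_len),
                        conv_kernels = as.integer(conv_kernels),
                        kernel_widths = as.integer(kernel_widths),
                        pool_sizes = as.integer(pool_sizes),
                        dense_units = as.integer(dense_units),
                        output_units = as.integer(output_units)),
                   class = "enh_model_config")
  nn_lengths(cfg)  # validates the length pipeline
  cfg
}

#' Full-scale reference architecture
#'
#' Kernel counts 320/320/240/240/480 and a 180-unit dense layer on 1000-bp
#' input; kernel widths and pool sizes are fixed by the deterministic
#' constraint search of [solve_reference_architecture()] so that the
#' trainable-parameter total is 3,631,401.
#'
#' @return An `enh_model_config`.
#' @export
reference_config <- function() {
  model_config(input_len = 1000L,
               conv_kernels = c(320L, 320L, 240L, 240L, 480L),
               kernel_widths = c(3L, 4L, 4L, 2L, 4L),
               pool_sizes = c(1L, 1L, 1L, 5L, 7L),
               dense_units = 180L,
               output_units = 1L)
}

#' Count trainable parameters of an architecture
#'
#' Closed-form count: each conv layer contributes
#' `in_channels * width * kernels + kernels`, the dense layer
#' `flattened_length * dense_units + dense_units`, and the output layer
#' `dense_units * output_units + output_units`, where the flattened length
#' follows valid convolutions (`len - width + 1`) and floor-divided
#' non-overlapping pooling.
#'
#' @param config An [model_config()] object.
#' @return Integer parameter total.
#' @examples
#' cfg <- model_config(20, 8L, 5L, 1L, dense_units = 1L, output_units = 1L)
#' count_parameters(cfg)
#' @export
count_parameters <- function(config) {
  lens <- nn_lengths(config)
  in_ch <- c(4L, config$conv_kernels[-length(config$conv_kernels)])
  conv_p <- sum(in_ch * config$kernel_widths * config$conv_kernels +
                config$conv_kernels)
  dense_p <- lens$flat * config$dense_units + config$dense_units
  out_p <- config$dense_units * config$output_units + config$output_units
  as.integer(conv_p + dense_p + out_p)
}

#' Solve for an architecture matching a target parameter count
#'
#' Deterministic constraint search over kernel widths, pool sizes and
#' output units, with kernel counts and dense width fixed.  The search is
#' lexicographic: widths are enumerated in ascending order, then output
#' units, then the lexicographically smallest pool assignment reaching the
#' required flattened length; the first exact solution is returned.  When
#' no in-bounds configuration matches exactly, `NULL` is returned with a
#' message reporting the nearest achievable count encountered.
#'
#' @param target_params Target trainable-parameter total.
#' @param conv_kernels Fixed kernel counts.
#' @param dense_units Fixed dense width.
#' @param input_len Input length in bp.
#' @param width_range,pool_range,output_range Integer search bounds.
#' @return An `enh_model_config` with
#'   `count_parameters(config) == target_params`, or `NULL`.
#' @export
solve_reference_architecture <- function(target_params = 3631401L,
                                         conv_kernels = c(320L, 320L, 240L,
                                                          240L, 480L),
                                         dense_units = 180L,
                                         input_len = 1000L,
                                         width_range = 2:26,
                                         pool_range = 1:8,
                                         output_range = 1:2) {
  nl <- length(conv_kernels)
  in_ch <- c(4L, conv_kernels[-nl])
  k_last <- conv_kernels[nl]
  # conv parameter contribution of layer i at each candidate width
  a <- lapply(seq_len(nl), function(i) {
    in_ch[i] * conv_kernels[i] * width_range + conv_kernels[i]
  })
  # lexicographically smallest pools achieving flattened length L, or NULL
  solve_pools <- function(widths, L) {
    rec <- function(i, len) {
      if (i > nl) return(if (len == L) integer(0) else NULL)
      len2 <- len - widths[i] + 1L
      if (len2 < 1L) return(NULL)
      rem_w <- if (i < nl) sum(widths[(i + 1):nl]) else 0L
      if (len2 - rem_w + (nl - i) < L) return(NULL)  # even all-1 pools fail
      for (p in pool_range) {
        res <- rec(i + 1L, len2 %/% p)
        if (!is.null(res)) return(c(p, res))
      }
      NULL
    }
    rec(1L, input_len)
  }
  best <- NULL
  best_diff <- Inf
  nw <- length(width_range)
  widx <- rep(1L, nl)
  repeat {
    widths <- width_range[widx]
    conv_p <- sum(vapply(seq_len(nl), function(i) a[[i]][widx[i]], 0))
    for (u in output_range) {
      resid <- target_params - conv_p - dense_units -
        (dense_units * u + u)
      L_real <- resid / (k_last * dense_units)
      for (L in unique(c(floor(L_real), ceiling(L_real)))) {
        if (L < 1) next
        pools <- solve_pools(widths, L)
        if (is.null(pools)) next
        cfg <- model_config(input_len, conv_kernels, widths, pools,
                            dense_units, u)
        got <- count_parameters(cfg)
        if (got == target_params) return(cfg)
        if (abs(got - target_params) < best_diff) {
          best_diff <- abs(got - target_params)
          best <- got
        }
      }
    }
    # advance width index vector lexicographically (last index fastest)
    i <- nl
    while (i >= 1L) {
      widx[i] <- widx[i] + 1L
      if (widx[i] <= nw) break
      widx[i] <- 1L
      i <- i - 1L
    }
    if (i < 1L) break
  }
  message("no architecture in bounds reaches ", target_params,
          " parameters",
          if (!is.null(best)) paste0("; nearest achievable count: ", best))
  NULL
}

#' Fit the convolutional enhancer activity scorer
#'
#' Trains a small convolutional network to discriminate enhancer-positive
#' from background sequences.  The data split is by chromosome: sequences
#' on chr8 and chr9 are held out as the test set, chr6 is the validation
#' set used for early stopping, and all remaining chromosomes train the
#' model.  Every training sample is presented in both orientations
#' (sequence and reverse complement).  Optimisation is Adam on binary
#' cross-entropy with early stopping on validation loss.
#'
#' @param sequences Character vector of sequences, all of the config's
#'   input length.
#' @param labels 0/1 integer vector (1 = enhancer).
#' @param chrom Chromosome label per sequence (e.g. `"chr8"`), used for
#'   the train/validation/test split.
#' @param config An [model_config()]; default is the small desk-scale
#'   architecture.
#' @param seed RNG seed controlling initialisation and batch order.
#' @param epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param patience Early-stopping patience in epochs.
#' @param verbose Print per-epoch losses.
#' @return Object of class `enhancer_cnn` with elements `config`, `net`
#'   (weights), `history`, `metrics` (held-out test auROC/auPRC),
#'   `split`, and `seed`.
#' @seealso [predict.enhancer_cnn()], [score()], [calibrate_threshold()]
#' @export
enhancer_cnn <- function(sequences, labels, chrom,
                         config = model_config(),
                         seed = 1L, epochs = 15L, batch_size = 64L,
                         lr = 0.01, patience = 4L, verbose = FALSE) {
  stopifnot(length(sequences) == length(labels),
            length(sequences) == length(chrom))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  test_i <- chrom %in% c("chr8", "chr9")
  val_i <- chrom == "chr6"
  train_i <- !(test_i | val_i)
  for (nm in c("training", "validation", "test")) {
    idx <- switch(nm, training = train_i, validation = val_i,
                  test = test_i)
    if (length(unique(labels[idx])) < 2L) {
      stop("the ", nm, " split does not contain both classes")
    }
  }
  # augmentation: both orientations of every training sequence
  tr_seq <- c(sequences[train_i], revcomp(sequences[train_i]))
  tr_y <- rep(labels[train_i], 2L)
  Xtr <- encode_batch(tr_seq, config$input_len)
  Xval <- encode_batch(sequences[val_i], config$input_len)
  yval <- labels[val_i]
  net <- nn_init(config, seed = seed)
  state <- adam_init(net)
  n <- length(tr_y)
  best_val <- Inf; best_net <- net; wait <- 0L; t <- 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  set.seed(seed + 1L)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (s in seq(1L, n, by = batch_size)) {
      idx <- ord[s:min(s + batch_size - 1L, n)]
      fw <- nn_forward(net, Xtr[idx, , , drop = FALSE], keep = TRUE)
      ep_loss <- ep_loss + bce_loss(fw$prob, tr_y[idx]); nb <- nb + 1L
      g <- nn_backward(net, fw$cache, tr_y[idx])
      t <- t + 1L
      r <- adam_step(net, g, state, lr, t)
      net <- r$net; state <- r$state
    }
    vp <- nn_forward(net, Xval)$prob
    vl <- bce_loss(vp, yval)
    history <- rbind(history, data.frame(epoch = ep,
                                         train_loss = ep_loss / nb,
                                         val_loss = vl))
    if (verbose) {
      message(sprintf("epoch %d: train %.4f val %.4f", ep,
                      ep_loss / nb, vl))
    }
    if (vl < best_val - 1e-5) {
      best_val <- vl; best_net <- net; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  obj <- structure(list(config = config, net = best_net,
                        history = history, seed = seed,
                        split = c(train = sum(train_i), val = sum(val_i),
                                  test = sum(test_i))),
                   class = "enhancer_cnn")
  test_scores <- score(obj, sequences[test_i])
  obj$metrics <- c(auroc = auroc(test_scores, labels[test_i]),
                   auprc = auprc(test_scores, labels[test_i]))
  obj
}

#' @export
print.enhancer_cnn <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Convolutional enhancer scorer: %d-bp input, %d conv layer(s) (%s kernels), %d dense units\n",
    cfg$input_len, length(cfg$conv_kernels),
    paste(cfg$conv_kernels, collapse = "/"), cfg$dense_units))
  cat(sprintf("Trainable parameters: %s\n",
              format(count_parameters(cfg), big.mark = ",")))
  if (!is.null(x$metrics)) {
    cat(sprintf("Held-out test (chr8/9): auROC %.3f, auPRC %.3f\n",
                x$metrics["auroc"], x$metrics["auprc"]))
  }
  invisible(x)
}

#' @export
summary.enhancer_cnn <- function(object, ...) {
  print(object)
  cat(sprintf("Split sizes: train %d, validation (chr6) %d, test %d\n",
              object$split["train"], object$split["val"],
              object$split["test"]))
  cat(sprintf("Epochs run: %d (best validation loss %.4f)\n",
              max(object$history$epoch), min(object$history$val_loss)))
  invisible(object)
}

#' Predict activity probabilities for sequences
#'
#' Scores are the average of the forward and reverse-complement network
#' outputs, which makes the score exactly invariant under reverse
#' complementation.
#'
#' @param object A fitted [enhancer_cnn()].
#' @param newdata Character vector of sequences of the model's input
#'   length (`N` is encoded as 0.25 per base).
#' @param ... Unused.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
predict.enhancer_cnn <- function(object, newdata, ...) {
  if (length(newdata) == 0L) return(numeric(0))
  bad <- nchar(newdata) != object$config$input_len
  if (any(bad)) {
    stop(sprintf("sequence length %d does not match model input length %d",
                 nchar(newdata[bad][1L]), object$config$input_len))
  }
  out <- numeric(length(newdata))
  chunk <- 256L
  for (s in seq(1L, length(newdata), by = chunk)) {
    idx <- s:min(s + chunk - 1L, length(newdata))
    Xf <- encode_batch(newdata[idx], object$config$input_len)
    Xr <- encode_batch(revcomp(newdata[idx]), object$config$input_len)
    out[idx] <- (nn_forward(object$net, Xf)$prob +
                   nn_forward(object$net, Xr)$prob) / 2
  }
  out
}

#' Score sequences with a fitted scorer
#'
#' Generic dispatching on the scorer type: [enhancer_cnn()] models and
#' [pwm_scorer()] objects both implement it.  Values are probabilities in
#' \[0, 1\]; larger means more likely to be an active enhancer.
#'
#' @param object A scorer.
#' @param sequences Character vector of sequences.
#' @param ... Passed to methods.
#' @return Numeric vector of scores.
#' @export
score <- function(object, sequences, ...) UseMethod("score")

#' @export
score.enhancer_cnn <- function(object, sequences, ...) {
  predict(object, sequences)
}

#' PWM-based toy activity scorer
#'
#' Maps the best log-odds motif match (over all supplied PWMs and both
#' strands) through a logistic link centred at the PWM hit threshold, so a
#' sequence scores above 0.5 exactly when it contains a motif hit.  Used
#' as a transparent stand-in scorer with known ground truth.
#'
#' @param pwms List of calibrated [pwm()] objects.
#' @param scale Logistic scale (log-odds units per logit).
#' @return Object of class `pwm_scorer`; its natural activity threshold is
#'   0.5.
#' @export
pwm_scorer <- function(pwms, scale = 1) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  if (any(vapply(pwms, function(p) is.na(p$threshold), TRUE))) {
    stop("all PWMs must be calibrated before building a scorer")
  }
  structure(list(pwms = pwms, scale = scale), class = "pwm_scorer")
}

#' @export
print.pwm_scorer <- function(x, ...) {
  cat(sprintf("PWM scorer over %d motif(s): %s\n", length(x$pwms),
              paste(vapply(x$pwms, `[[`, "", "name"), collapse = ", ")))
  invisible(x)
}

#' @export
score.pwm_scorer <- function(object, sequences, ...) {
  vapply(sequences, function(s) {
    codes <- seq_codes(s)
    best <- -Inf
    for (p in object$pwms) {
      lo <- pwm_logodds(p)
      w <- nrow(lo)
      if (length(codes) < w) next
      lo_rc <- lo[rev(seq_len(w)), c(4L, 3L, 2L, 1L), drop = FALSE]
      m <- max(scan_scores(codes, lo), scan_scores(codes, lo_rc))
      best <- max(best, (m - p$threshold) / object$scale)
    }
    1 / (1 + exp(-best))
  }, 0, USE.NAMES = FALSE)
}

#' @export
predict.pwm_scorer <- function(object, newdata, ...) score(object, newdata)

#' Calibrate an activity score threshold at a target false-positive rate
#'
#' Returns the smallest observed score such that the fraction of negative
#' scores at or above it does not exceed `fpr`.  When every candidate is
#' too permissive (e.g. all negatives share one score), a value just above
#' the maximum is returned so that no negative passes.
#'
#' @param negative_scores Scores of negative (background) sequences; at
#'   least 10 are expected.
#' @param fpr Target false-positive rate (default 0.1).
#' @return Object of class `score_threshold` with fields `value` and
#'   `fpr`.
#' @examples
#' calibrate_threshold(seq(0.01, 0.10, by = 0.01), fpr = 0.1)
#' @export
calibrate_threshold <- function(negative_scores, fpr = 0.1) {
  if (length(negative_scores) == 0L) stop("no negative scores supplied")
  if (length(negative_scores) < 10L) {
    warning("fewer than 10 negative scores; calibration will be coarse")
  }
  s_sorted <- sort(negative_scores)
  cand <- unique(s_sorted)
  frac_ge <- (length(s_sorted) - match(cand, s_sorted) + 1L) /
    length(s_sorted)
  ok <- which(frac_ge <= fpr)
  value <- if (length(ok)) cand[ok[1L]] else max(s_sorted) + 1e-9
  structure(list(value = value, fpr = fpr), class = "score_threshold")
}

#' @export
print.score_threshold <- function(x, ...) {
  cat(sprintf("Activity threshold %.4g (target FPR %.3g)\n",
              x$value, x$fpr))
  invisible(x)
}

# Accept either a score_threshold or a bare numeric cutoff.
thr_value <- function(thr) {
  if (inherits(thr, "score_threshold")) thr$value else as.numeric(thr)
}

#' Score change caused by a set of single-nucleotide edits
#'
#' @param scorer A scorer ([enhancer_cnn()] or [pwm_scorer()]).
#' @param base_seq Reference sequence.
#' @param positions 1-based positions of the edits.
#' @param alleles Replacement bases, each different from the reference
#'   base at its position.
#' @return `score(edited) - score(base)`; `base_seq` is not modified.
#' @export
delta_score <- function(scorer, base_seq, positions, alleles) {
  if (length(positions) == 0L) return(0)
  edited <- apply_edits(base_seq, positions, alleles)
  score(scorer, edited) - score(scorer, base_seq)
}

#' Accuracy of allele-direction prediction as a function of score margin
#'
#' For each margin `m`, restricts to variant pairs whose absolute score
#' difference is at least `m` and reports the accuracy of predicting the
#' higher-activity allele by the sign of the score difference, together
#' with the fraction of pairs retained.
#'
#' @param deltas Predicted score differences (allele A minus allele B).
#' @param observed_directions Observed direction labels, +1 or -1.
#' @param margins Numeric grid of margins.
#' @return `data.frame` with columns `margin`, `accuracy`, `coverage`;
#'   `accuracy` is `NA` where no pair clears the margin.
#' @export
allele_effect_accuracy <- function(deltas, observed_directions,
                                   margins = seq(0, 0.5, by = 0.05)) {
  stopifnot(length(deltas) == length(observed_directions))
  if (!all(observed_directions %in% c(-1, 1))) {
    stop("observed_directions must be +1/-1")
  }
  do.call(rbind, lapply(margins, function(m) {
    sel <- abs(deltas) >= m
    data.frame(margin = m,
               accuracy = if (any(sel)) {
                 mean(sign(deltas[sel]) == observed_directions[sel])
               } else NA_real_,
               coverage = mean(sel))
  }))
}
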