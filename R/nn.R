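# Internal neural-network machinery: 1-D convolution via im2col, ReLU,
# non-overlapping max pooling, a dense ReLU layer and a sigmoid output,
# trained with Adam on binary cross-entropy.  Written in base R matrix
# algebra; shapes follow (batch, length, channels).

# Per-layer output lengths for a config; errors if pooling exhausts the
# sequence.  Returns list(conv_out, pool_out, flat).
nn_lengths <- function(config) {
  len <- config$input_len
  conv_out <- integer(0)
  pool_out <- integer(0)
  for (i in seq_along(config$conv_kernels)) {
    len <- len - config$kernel_widths[i] + 1L
    if (len < 1L) {
      stop(sprintf("conv layer %d reduces length below 1", i))
    }
    conv_out <- c(conv_out, len)
    len <- len %/% config$pool_sizes[i]
    if (len < 1L) {
      stop(sprintf("pool layer %d reduces length below 1", i))
    }
    pool_out <- c(pool_out, len)
  }
  list(conv_out = conv_out, pool_out = pool_out,
       flat = len * config$conv_kernels[length(config$conv_kernels)])
}

# Allocate and initialise all weights (He init, zero biases).
nn_init <- function(config, seed = 1L) {
  set.seed(seed)
  in_ch <- 4L
  conv <- vector("list", length(config$conv_kernels))
  for (i in seq_along(conv)) {
    w <- config$kernel_widths[i]
    k <- config$conv_kernels[i]
    fan_in <- in_ch * w
    conv[[i]] <- list(
      W = matrix(rnorm(fan_in * k, 0, sqrt(2 / fan_in)), fan_in, k),
      b = numeric(k))
    in_ch <- k
  }
  flat <- nn_lengths(config)$flat
  dense <- list(
    W = matrix(rnorm(flat * config$dense_units, 0, sqrt(2 / flat)),
               flat, config$dense_units),
    b = numeric(config$dense_units))
  out <- list(
    W = matrix(rnorm(config$dense_units * config$output_units, 0,
                     sqrt(2 / config$dense_units)),
               config$dense_units, config$output_units),
    b = numeric(config$output_units))
  list(config = config, conv = conv, dense = dense, out = out)
}

# Trainable parameter total of an instantiated network, by summing the
# lengths of every allocated weight and bias array.  Serves as the
# independent counter checked against count_parameters().
nn_num_params <- function(net) {
  n <- 0L
  for (l in net$conv) n <- n + length(l$W) + length(l$b)
  n + length(net$dense$W) + length(net$dense$b) +
    length(net$out$W) + length(net$out$b)
}

# im2col index matrix: (w*C) x outL of flat (len*C) column indices.
im2col_idx <- function(len, w, C) {
  j <- rep(seq_len(w), times = C)
  ch <- rep(seq_len(C), each = w)
  base <- (j - 1L) + (ch - 1L) * len
  outer(base, seq_len(len - w + 1L), "+")
}

# One-hot encode sequences into a (B, L, 4) array.
encode_batch <- function(seqs, input_len) {
  B <- length(seqs)
  X <- array(0, c(B, input_len, 4L))
  for (b in seq_len(B)) {
    if (nchar(seqs[b]) != input_len) {
      stop(sprintf("sequence %d has length %d, expected %d",
                   b, nchar(seqs[b]), input_len))
    }
    X[b, , ] <- one_hot(seqs[b])
  }
  X
}

# Forward pass.  Returns list(prob, cache); cache is NULL unless keep=TRUE.
nn_forward <- function(net, X, keep = FALSE) {
  cfg <- net$config
  B <- dim(X)[1L]
  cache <- if (keep) list(layers = vector("list", length(net$conv)))
           else NULL
  for (i in seq_along(net$conv)) {
    len <- dim(X)[2L]; C <- dim(X)[3L]
    w <- cfg$kernel_widths[i]; K <- cfg$conv_kernels[i]
    p <- cfg$pool_sizes[i]
    outL <- len - w + 1L
    idx <- im2col_idx(len, w, C)
    Xf <- X; dim(Xf) <- c(B, len * C)
    A <- Xf[, as.vector(idx), drop = FALSE]
    dim(A) <- c(B, w * C, outL)
    A <- aperm(A, c(1L, 3L, 2L))
    dim(A) <- c(B * outL, w * C)
    Z <- A %*% net$conv[[i]]$W
    Z <- sweep(Z, 2L, net$conv[[i]]$b, "+")
    H <- pmax(Z, 0)
    dim(H) <- c(B, outL, K)
    poolL <- outL %/% p
    Ht <- H[, seq_len(p * poolL), , drop = FALSE]
    dim(Ht) <- c(B, p, poolL, K)
    M <- array(Ht[, 1L, , ], c(B, poolL, K))
    arg <- array(1L, c(B, poolL, K))
    if (p > 1L) {
      for (q in 2:p) {
        S <- array(Ht[, q, , ], c(B, poolL, K))
        upd <- S > M
        arg[upd] <- q
        M[upd] <- S[upd]
      }
    }
    if (keep) {
      cache$layers[[i]] <- list(A = A, relu = Z > 0, arg = arg,
                                len = len, C = C, outL = outL,
                                poolL = poolL, idx = idx)
    }
    X <- M
  }
  Fl <- X; dim(Fl) <- c(B, prod(dim(X)[2:3]))
  D <- sweep(Fl %*% net$dense$W, 2L, net$dense$b, "+")
  Hd <- pmax(D, 0)
  O <- sweep(Hd %*% net$out$W, 2L, net$out$b, "+")
  prob <- 1 / (1 + exp(-O[, 1L]))
  if (keep) {
    cache$flat <- Fl; cache$D <- D; cache$Hd <- Hd; cache$prob <- prob
    cache$B <- B
  }
  list(prob = prob, cache = cache)
}

# Backward pass for binary cross-entropy; returns gradients shaped like
# the weight lists.
nn_backward <- function(net, cache, y) {
  cfg <- net$config
  B <- cache$B
  dO <- matrix((cache$prob - y) / B, B, 1L)
  g <- list(out = list(W = crossprod(cache$Hd, dO), b = colSums(dO)),
            dense = NULL, conv = vector("list", length(net$conv)))
  dHd <- dO %*% t(net$out$W)
  dD <- dHd * (cache$D > 0)
  g$dense <- list(W = crossprod(cache$flat, dD), b = colSums(dD))
  dFl <- dD %*% t(net$dense$W)
  nl <- length(net$conv)
  lastK <- cfg$conv_kernels[nl]
  dM <- array(dFl, c(B, ncol(dFl) / lastK, lastK))
  for (i in rev(seq_len(nl))) {
    ly <- cache$layers[[i]]
    K <- cfg$conv_kernels[i]; p <- cfg$pool_sizes[i]
    w <- cfg$kernel_widths[i]
    # un-pool: send gradient to the argmax position of each window
    dH <- numeric(B * ly$outL * K)
    nEl <- B * ly$poolL * K
    bb <- rep(seq_len(B), times = ly$poolL * K)
    gg <- rep(rep(seq_len(ly$poolL), each = B), times = K)
    kk <- rep(seq_len(K), each = B * ly$poolL)
    pos <- (gg - 1L) * p + as.vector(ly$arg)
    li <- bb + B * (pos - 1L) + B * ly$outL * (kk - 1L)
    dH[li] <- as.vector(dM)
    dim(dH) <- c(B * ly$outL, K)
    dZ <- dH * ly$relu
    g$conv[[i]] <- list(W = crossprod(ly$A, dZ), b = colSums(dZ))
    if (i > 1L) {
      dA <- dZ %*% t(net$conv[[i]]$W)
      dX <- matrix(0, B, ly$len * ly$C)
      for (o in seq_len(ly$outL)) {
        rows <- (o - 1L) * B + seq_len(B)
        cols <- ly$idx[, o]
        dX[, cols] <- dX[, cols] + dA[rows, , drop = FALSE]
      }
      prevK <- cfg$conv_kernels[i - 1L]
      dM <- array(dX, c(B, ly$len, prevK))
    }
  }
  g
}

# Adam optimiser step over the nested gradient structure.
adam_step <- function(net, g, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  upd <- function(wname, W, gW, m, v) {
    m <- beta1 * m + (1 - beta1) * gW
    v <- beta2 * v + (1 - beta2) * gW^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(W = W - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  for (i in seq_along(net$conv)) {
    for (nm in c("W", "b")) {
      key <- paste0("conv", i, nm)
      r <- upd(key, net$conv[[i]][[nm]], g$conv[[i]][[nm]],
               state$m[[key]], state$v[[key]])
      net$conv[[i]][[nm]] <- r$W
      state$m[[key]] <- r$m; state$v[[key]] <- r$v
    }
  }
  for (part in c("dense", "out")) {
    for (nm in c("W", "b")) {
      key <- paste0(part, nm)
      r <- upd(key, net[[part]][[nm]], g[[part]][[nm]],
               state$m[[key]], state$v[[key]])
      net[[part]][[nm]] <- r$W
      state$m[[key]] <- r$m; state$v[[key]] <- r$v
    }
  }
  list(net = net, state = state)
}

adam_init <- function(net) {
  zeros <- function(x) {
    if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
  }
  m <- list()
  for (i in seq_along(net$conv)) {
    m[[paste0("conv", i, "W")]] <- zeros(net$conv[[i]]$W)
    m[[paste0("conv", i, "b")]] <- zeros(net$conv[[i]]$b)
  }
  for (part in c("dense", "out")) {
    m[[paste0(part, "W")]] <- zeros(net[[part]]$W)
    m[[paste0(part, "b")]] <- zeros(net[[part]]$b)
  }
  list(m = m, v = m)
}

# Mean binary cross-entropy (clipped for numerical safety).
bce_loss <- function(prob, y) {
  p <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Area under the ROC curve via the rank (Mann-Whitney) identity.
auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0L || length(neg) == 0L) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# Area under the precision-recall curve (step interpolation).
auprc <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  rec <- tp / sum(y)
  sum(prec[y == 1]) / sum(y)
}
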