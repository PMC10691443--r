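# Compact densely connected convolutional regression engine.
#
# Pure-R implementation backed by BLAS matrix multiplies. Activations are
# kept as (H*W*N) x C matrices (rows: pixel position fastest, then image;
# columns: channels), so 3x3 convolution is nine row-indexed GEMM
# accumulations against precomputed shift-index vectors, dense blocks
# concatenate by cbind, transitions are 1x1 GEMMs with 2x2 average pooling,
# and a global average pool feeds one linear output. Training is plain
# backpropagation with Adam on mean squared error.

# Per-geometry index caches (conv shifts, pooling gathers).
.geom_cache <- new.env(parent = emptyenv())

# Nine shift-index vectors for a 3x3 kernel on an H x W x N stack; invalid
# (out-of-image) positions point at a dummy zero row M+1.
conv_shift_idx <- function(H, W, N) {
  key <- sprintf("c_%d_%d_%d", H, W, N)
  hit <- .geom_cache[[key]]
  if (!is.null(hit)) return(hit)
  M <- H * W * N
  h <- rep_len(rep(seq_len(H), W), M)
  w <- rep_len(rep(seq_len(W), each = H), M)
  n0 <- rep(seq_len(N) - 1L, each = H * W) * (H * W)
  idx <- vector("list", 9L)
  k <- 0L
  for (dx in -1:1) for (dy in -1:1) {
    k <- k + 1L
    hh <- h + dy; ww <- w + dx
    ok <- hh >= 1L & hh <= H & ww >= 1L & ww <= W
    id <- hh + (ww - 1L) * H + n0
    id[!ok] <- M + 1L
    idx[[k]] <- id
  }
  .geom_cache[[key]] <- idx
  idx
}

# Four gather-index vectors mapping each 2x2 output cell to its inputs.
pool_gather_idx <- function(H, W, N) {
  key <- sprintf("p_%d_%d_%d", H, W, N)
  hit <- .geom_cache[[key]]
  if (!is.null(hit)) return(hit)
  H2 <- H %/% 2L; W2 <- W %/% 2L
  M2 <- H2 * W2 * N
  i <- rep_len(rep(seq_len(H2), W2), M2)
  j <- rep_len(rep(seq_len(W2), each = H2), M2)
  n0 <- rep(seq_len(N) - 1L, each = H2 * W2) * (H * W)
  at <- function(di, dj) (2L * i - 1L + di) + (2L * j - 2L + dj) * H + n0
  out <- list(at(0L, 0L), at(1L, 0L), at(0L, 1L), at(1L, 1L))
  .geom_cache[[key]] <- out
  out
}

conv3_forward <- function(x, H, W, N, Wmat, b) {
  C <- ncol(x)
  idx <- conv_shift_idx(H, W, N)
  xz <- rbind(x, 0)
  y <- matrix(b, nrow(x), length(b), byrow = TRUE)
  for (k in 1:9) {
    rows <- ((k - 1L) * C + 1L):(k * C)
    y <- y + xz[idx[[k]], , drop = FALSE] %*% Wmat[rows, , drop = FALSE]
  }
  y
}

conv3_backward <- function(x, H, W, N, Wmat, dy) {
  C <- ncol(x)
  idx <- conv_shift_idx(H, W, N)
  xz <- rbind(x, 0)
  dW <- matrix(0, 9L * C, ncol(dy))
  dxz <- matrix(0, nrow(x) + 1L, C)
  for (k in 1:9) {
    rows <- ((k - 1L) * C + 1L):(k * C)
    dW[rows, ] <- crossprod(xz[idx[[k]], , drop = FALSE], dy)
    dxz[idx[[k]], ] <- dxz[idx[[k]], , drop = FALSE] +
      dy %*% t(Wmat[rows, , drop = FALSE])
  }
  list(dW = dW, db = colSums(dy), dx = dxz[-nrow(dxz), , drop = FALSE])
}

pool2_forward <- function(x, H, W, N) {
  g <- pool_gather_idx(H, W, N)
  (x[g[[1]], , drop = FALSE] + x[g[[2]], , drop = FALSE] +
     x[g[[3]], , drop = FALSE] + x[g[[4]], , drop = FALSE]) / 4
}

pool2_backward <- function(dy, H, W, N) {
  g <- pool_gather_idx(H, W, N)
  dx <- matrix(0, H * W * N, ncol(dy))
  q <- dy / 4
  dx[g[[1]], ] <- q; dx[g[[2]], ] <- q
  dx[g[[3]], ] <- q; dx[g[[4]], ] <- q
  dx
}

relu <- function(x) x * (x > 0)

# ---- architecture ----------------------------------------------------------

#' Network configuration for the viability decoder
#'
#' A compact dense-connectivity architecture: a 3x3 stem convolution
#' followed by `stem_pools` 2x2 average poolings, `blocks` dense blocks of
#' `layers_per_block` 3x3 convolutions each adding `growth` channels to a
#' running concatenation, 1x1-convolution transitions compressing channels
#' by `compression` and halving resolution between blocks, then global
#' average pooling and one linear output (unbounded regression; labels are
#' % viability).
#'
#' @param input_size square input resolution in px (images must be
#'   preprocessed to this size; must be divisible by
#'   `2^(stem_pools + blocks - 1)`).
#' @param stem_channels channels after the stem convolution.
#' @param stem_pools 2x2 average poolings after the stem (default 2: the
#'   stem downsamples 4x before the first dense block, keeping dense-block
#'   convolutions cheap).
#' @param blocks number of dense blocks.
#' @param layers_per_block convolutions per dense block.
#' @param growth channels added by each dense layer.
#' @param compression channel-keep fraction at transitions.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param lr_decay multiplicative step decay applied to `lr` after
#'   `lr_decay_at * epochs` epochs (1 = constant rate); the late fine-tuning
#'   phase reduces shrinkage of the extreme predictions, which matters
#'   because the per-day normalization divides by the untreated well's
#'   prediction.
#' @param lr_decay_at fraction of `epochs` after which the decay applies.
#' @param train_seed seed controlling initialization and shuffling.
#' @return An object of class `net_config`.
#' @export
net_config <- function(input_size = 48, stem_channels = 16, stem_pools = 2,
                       blocks = 3, layers_per_block = 3, growth = 10,
                       compression = 0.5, epochs = 100, batch_size = 32,
                       lr = 2e-3, lr_decay = 0.2, lr_decay_at = 0.6,
                       train_seed = 1) {
  stopifnot(input_size >= 16, stem_channels > 0, stem_pools >= 1,
            blocks >= 1, layers_per_block >= 1, growth > 0, compression > 0,
            compression <= 1, epochs >= 1, batch_size >= 1, lr > 0)
  down <- 2^(stem_pools + blocks - 1L)
  if (input_size %% down != 0) {
    stopf("`input_size` must be divisible by 2^(stem_pools + blocks - 1) = %d",
          down)
  }
  structure(list(input_size = as.integer(input_size),
                 stem_channels = as.integer(stem_channels),
                 stem_pools = as.integer(stem_pools),
                 blocks = as.integer(blocks),
                 layers_per_block = as.integer(layers_per_block),
                 growth = as.integer(growth), compression = compression,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 lr_decay = lr_decay, lr_decay_at = lr_decay_at,
                 train_seed = as.integer(train_seed)),
            class = "net_config")
}

he_init <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, 0, sqrt(2 / n_in)), n_in, n_out)
}

# Initialize all parameters; uses the caller's RNG state.
init_params <- function(cfg) {
  p <- list(stem_W = he_init(9L, cfg$stem_channels),
            stem_b = numeric(cfg$stem_channels),
            blocks = vector("list", cfg$blocks),
            trans = vector("list", cfg$blocks - 1L))
  ch <- cfg$stem_channels
  for (b in seq_len(cfg$blocks)) {
    layers <- vector("list", cfg$layers_per_block)
    for (l in seq_len(cfg$layers_per_block)) {
      layers[[l]] <- list(W = he_init(9L * ch, cfg$growth),
                          b = numeric(cfg$growth))
      ch <- ch + cfg$growth
    }
    p$blocks[[b]] <- layers
    if (b < cfg$blocks) {
      out_ch <- max(1L, floor(ch * cfg$compression))
      p$trans[[b]] <- list(W = he_init(ch, out_ch), b = numeric(out_ch))
      ch <- out_ch
    }
  }
  p$head_w <- matrix(stats::rnorm(ch, 0, sqrt(1 / ch)), ch, 1)
  p$head_b <- 0
  p
}

# Forward pass. x: (H*W*N) x 1 matrix with geometry (H, W, N). Returns
# predictions and, when `keep_cache`, the activations needed for backprop.
net_forward <- function(params, cfg, x, H, W, N, keep_cache = FALSE) {
  cache <- list(x = x, H0 = H, W0 = W, N = N)
  z <- relu(conv3_forward(x, H, W, N, params$stem_W, params$stem_b))
  cache$stem <- z
  a <- z
  for (i in seq_len(cfg$stem_pools)) {
    a <- pool2_forward(a, H, W, N); H <- H %/% 2L; W <- W %/% 2L
  }
  cache$blocks <- vector("list", cfg$blocks)
  cache$trans_pre <- vector("list", cfg$blocks)
  cache$geom <- vector("list", cfg$blocks)
  for (b in seq_len(cfg$blocks)) {
    feats <- a
    for (l in seq_len(cfg$layers_per_block)) {
      lay <- params$blocks[[b]][[l]]
      feats <- cbind(feats,
                     relu(conv3_forward(feats, H, W, N, lay$W, lay$b)))
    }
    cache$blocks[[b]] <- feats
    cache$geom[[b]] <- c(H, W)
    if (b < cfg$blocks) {
      tp <- relu(sweep(feats %*% params$trans[[b]]$W, 2L,
                       params$trans[[b]]$b, `+`))
      cache$trans_pre[[b]] <- tp
      a <- pool2_forward(tp, H, W, N); H <- H %/% 2L; W <- W %/% 2L
    } else {
      a <- feats
    }
  }
  gap <- colMeans(array(a, c(H * W, N, ncol(a))))
  if (N == 1L) gap <- matrix(gap, 1L)
  cache$gap <- gap
  pred <- drop(gap %*% params$head_w) + params$head_b
  if (keep_cache) list(pred = pred, cache = cache) else list(pred = pred)
}

# Backward pass for gradients dpred (length N); returns a gradient list
# shaped like `params`.
net_backward <- function(params, cfg, cache, dpred) {
  g <- list(blocks = vector("list", cfg$blocks),
            trans = vector("list", cfg$blocks - 1L))
  N <- cache$N
  gap <- cache$gap
  g$head_w <- crossprod(gap, dpred)
  g$head_b <- sum(dpred)
  dgap <- matrix(dpred, ncol = 1L) %*% t(params$head_w)   # N x C

  hw <- prod(cache$geom[[cfg$blocks]])
  da <- dgap[rep(seq_len(N), each = hw), , drop = FALSE] / hw

  for (b in rev(seq_len(cfg$blocks))) {
    feats <- cache$blocks[[b]]
    H <- cache$geom[[b]][1]; W <- cache$geom[[b]][2]
    dfeats <- da
    for (l in rev(seq_len(cfg$layers_per_block))) {
      k <- cfg$growth
      in_ch <- ncol(feats) - (cfg$layers_per_block - l + 1L) * k
      rng <- (in_ch + 1L):(in_ch + k)
      y <- feats[, rng, drop = FALSE]
      dy <- dfeats[, rng, drop = FALSE] * (y > 0)
      x_l <- feats[, seq_len(in_ch), drop = FALSE]
      bw <- conv3_backward(x_l, H, W, N, params$blocks[[b]][[l]]$W, dy)
      g$blocks[[b]][[l]] <- list(W = bw$dW, b = bw$db)
      dfeats <- dfeats[, seq_len(in_ch), drop = FALSE] + bw$dx
    }
    if (b > 1L) {
      tb <- b - 1L
      tp <- cache$trans_pre[[tb]]
      Hp <- cache$geom[[tb]][1]; Wp <- cache$geom[[tb]][2]
      dtp <- pool2_backward(dfeats, Hp, Wp, N) * (tp > 0)
      prev <- cache$blocks[[tb]]
      g$trans[[tb]] <- list(W = crossprod(prev, dtp), b = colSums(dtp))
      da <- dtp %*% t(params$trans[[tb]]$W)
    } else {
      Hs <- cache$H0; Ws <- cache$W0
      dstem <- dfeats
      for (i in rev(seq_len(cfg$stem_pools))) {
        hh <- Hs %/% 2^(i - 1L); ww <- Ws %/% 2^(i - 1L)
        dstem <- pool2_backward(dstem, hh, ww, N)
      }
      dstem <- dstem * (cache$stem > 0)
      bw <- conv3_backward(cache$x, Hs, Ws, N, params$stem_W, dstem)
      g$stem_W <- bw$dW
      g$stem_b <- bw$db
    }
  }
  g
}

# ---- flat parameter utilities for the optimizer ---------------------------

flatten_params <- function(p, cfg) {
  out <- list(p$stem_W, p$stem_b)
  for (b in seq_len(cfg$blocks)) {
    for (l in seq_len(cfg$layers_per_block)) {
      out <- c(out, list(p$blocks[[b]][[l]]$W, p$blocks[[b]][[l]]$b))
    }
    if (b < cfg$blocks) out <- c(out, list(p$trans[[b]]$W, p$trans[[b]]$b))
  }
  c(out, list(p$head_w, p$head_b))
}

unflatten_params <- function(flat, template, cfg) {
  i <- 0L
  nxt <- function() { i <<- i + 1L; flat[[i]] }
  p <- template
  p$stem_W <- nxt(); p$stem_b <- nxt()
  for (b in seq_len(cfg$blocks)) {
    for (l in seq_len(cfg$layers_per_block)) {
      p$blocks[[b]][[l]]$W <- nxt(); p$blocks[[b]][[l]]$b <- nxt()
    }
    if (b < cfg$blocks) { p$trans[[b]]$W <- nxt(); p$trans[[b]]$b <- nxt() }
  }
  p$head_w <- nxt(); p$head_b <- nxt()
  p
}

adam_step <- function(state, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (i in seq_along(grads)) {
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * grads[[i]]
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * grads[[i]]^2
    state$theta[[i]] <- state$theta[[i]] -
      lr * (state$m[[i]] / corr1) / (sqrt(state$v[[i]] / corr2) + eps)
  }
  state
}

# Stack a list of HxW matrices into the (H*W*N) x 1 training layout.
stack_images <- function(images) {
  matrix(unlist(images, use.names = FALSE), ncol = 1L)
}

# Gather rows of the stacked layout belonging to images `sel` (1-based).
select_images <- function(x, hw, sel) {
  rows <- rep((sel - 1L) * hw, each = hw) + rep_len(seq_len(hw), hw * length(sel))
  x[rows, , drop = FALSE]
}

predict_batches <- function(params, cfg, x, H, W, n, batch = 64L) {
  pred <- numeric(n)
  hw <- H * W
  for (start in seq(1L, n, by = batch)) {
    sel <- start:min(start + batch - 1L, n)
    pred[sel] <- net_forward(params, cfg, select_images(x, hw, sel),
                             H, W, length(sel))$pred
  }
  pred
}
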