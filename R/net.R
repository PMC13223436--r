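# The hybrid classifier: fire modules -> max pool -> patch tokens with
# position encoding -> self-attention blocks -> token grid reshaped back to a
# spatial map -> depthwise-separable residual block -> global average pooling
# -> fully-connected softmax head.  Dropout sites (after tokenization, after
# each attention block, after GAP) share one runtime-adjustable rate.

#' Architecture configuration
#'
#' The default is a deliberately small configuration suitable for CPU
#' experiments on 64x64 inputs: two fire modules (squeeze 8, expand 16+16),
#' 2x2 max pooling, 4x4 patches, a 64-dimensional token embedding with 4
#' attention heads and 2 attention blocks, and a 64-channel separable block.
#'
#' @param input_size square input side in pixels.
#' @param fire list of fire-module specs, each
#'   `list(squeeze=, expand1=, expand3=)`.
#' @param pool_size max-pooling window (input must divide evenly).
#' @param patch_size token patch side (pooled map must divide evenly).
#' @param embed_dim token embedding dimension.
#' @param n_heads attention heads (`embed_dim` must divide evenly).
#' @param n_attention_blocks number of stacked attention blocks.
#' @param sep_channels output channels of the separable residual block.
#' @param n_classes number of output classes (>= 2).
#' @param activation `"relu"` (default) or `"identity"`.
#' @param dropout default shared dropout rate used when no schedule is active.
#' @param dropout_bounds admissible range for the shared dropout rate.
#' @param dropout_sites where the shared rate applies: any subset of
#'   `"tokens"` (after patch embedding), `"attention"` (after each attention
#'   block), `"gap"` (after global average pooling).  The default is the
#'   classifier-head site only; stacking all three at rate 0.5 suppresses
#'   learning entirely at this model scale (see the methods vignette).
#' @return An object of class `"net_config"`.
#' @export
net_config <- function(input_size = 64L,
                       fire = list(list(squeeze = 8L, expand1 = 16L, expand3 = 16L),
                                   list(squeeze = 8L, expand1 = 16L, expand3 = 16L)),
                       pool_size = 2L, patch_size = 4L,
                       embed_dim = 64L, n_heads = 4L, n_attention_blocks = 2L,
                       sep_channels = 64L, n_classes = 4L,
                       activation = c("relu", "identity"),
                       dropout = 0.5, dropout_bounds = c(0.1, 0.6),
                       dropout_sites = "gap") {
  activation <- match.arg(activation)
  stopifnot(all(dropout_sites %in% c("tokens", "attention", "gap")))
  stopifnot(n_classes >= 2L, embed_dim %% n_heads == 0L,
            length(dropout_bounds) == 2L,
            dropout_bounds[1] > 0, dropout_bounds[2] < 1,
            dropout_bounds[1] < dropout_bounds[2])
  for (f in fire) stopifnot(f$squeeze >= 1L, f$expand1 >= 1L, f$expand3 >= 1L)
  if (input_size %% pool_size != 0L) {
    stop("input_size must be divisible by pool_size")
  }
  if ((input_size %/% pool_size) %% patch_size != 0L) {
    stop("pooled map must be divisible by patch_size")
  }
  grid <- input_size %/% pool_size %/% patch_size
  structure(list(input_size = as.integer(input_size), fire = fire,
                 pool_size = as.integer(pool_size),
                 patch_size = as.integer(patch_size),
                 embed_dim = as.integer(embed_dim),
                 n_heads = as.integer(n_heads),
                 n_attention_blocks = as.integer(n_attention_blocks),
                 sep_channels = as.integer(sep_channels),
                 n_classes = as.integer(n_classes),
                 activation = activation,
                 dropout = dropout, dropout_bounds = dropout_bounds,
                 dropout_sites = dropout_sites,
                 n_tokens = as.integer(grid * grid),
                 token_grid = as.integer(grid)),
            class = "net_config")
}

# Uniform fan-in init: U(-g/sqrt(fan_in), g/sqrt(fan_in)) with gain g =
# sqrt(6) before ReLU (He) and sqrt(3) for linear stages (Glorot-style), so
# activation variance is preserved through the stack.  Biases zero; position
# encodings small normal.
init_mat <- function(nr, nc, fan_in, gain = sqrt(3)) {
  matrix(stats::runif(nr * nc, -1, 1) * gain / sqrt(fan_in), nr, nc)
}

#' Initialize network parameters
#'
#' @param config a [net_config()].
#' @param seed integer seed for the init substream.
#' @return Named list of weight matrices / bias vectors.
#' @export
net_init <- function(config, seed = 1L) {
  with_seed(hash_seed(seed, "init"), {
    p <- list()
    cin <- 1L
    for (i in seq_along(config$fire)) {
      f <- config$fire[[i]]
      pre <- sprintf("fire%d_", i)
      p[[paste0(pre, "sq_W")]] <- init_mat(cin, f$squeeze, cin, sqrt(6))
      p[[paste0(pre, "sq_b")]] <- numeric(f$squeeze)
      p[[paste0(pre, "e1_W")]] <- init_mat(f$squeeze, f$expand1, f$squeeze,
                                           sqrt(6))
      p[[paste0(pre, "e1_b")]] <- numeric(f$expand1)
      p[[paste0(pre, "e3_W")]] <- init_mat(9L * f$squeeze, f$expand3,
                                           9L * f$squeeze, sqrt(6))
      p[[paste0(pre, "e3_b")]] <- numeric(f$expand3)
      cin <- f$expand1 + f$expand3
    }
    P2C <- config$patch_size^2 * cin
    p$tok_W <- init_mat(P2C, config$embed_dim, P2C)
    p$tok_b <- numeric(config$embed_dim)
    p$pos <- matrix(stats::rnorm(config$n_tokens * config$embed_dim, 0, 0.02),
                    config$n_tokens, config$embed_dim)
    d <- config$embed_dim
    for (j in seq_len(config$n_attention_blocks)) {
      pre <- sprintf("attn%d_", j)
      p[[paste0(pre, "Wq")]] <- init_mat(d, d, d)
      p[[paste0(pre, "Wk")]] <- init_mat(d, d, d)
      p[[paste0(pre, "Wv")]] <- init_mat(d, d, d)
      p[[paste0(pre, "Wo")]] <- init_mat(d, d, d)
      p[[paste0(pre, "bo")]] <- numeric(d)
    }
    p$sep_Wd <- init_mat(9L, d, 9L, sqrt(6))
    p$sep_bd <- numeric(d)
    p$sep_Wp <- init_mat(d, config$sep_channels, d, sqrt(6))
    p$sep_bp <- numeric(config$sep_channels)
    if (config$sep_channels != d) {
      p$sep_proj_W <- init_mat(d, config$sep_channels, d)
      p$sep_proj_b <- numeric(config$sep_channels)
    }
    # small output-layer init keeps the initial softmax near-uniform
    p$fc_W <- init_mat(config$n_classes, config$sep_channels,
                       config$sep_channels, gain = 0.3)
    p$fc_b <- numeric(config$n_classes)
    p
  })
}

# Convert a list of H x W image matrices into the batched (B*S) x 1 layout.
stack_images <- function(images) {
  B <- length(images)
  H <- nrow(images[[1]]); W <- ncol(images[[1]])
  X <- matrix(0, B * H * W, 1L)
  S <- H * W
  for (b in seq_len(B)) X[((b - 1L) * S + 1L):(b * S), 1L] <- as.vector(images[[b]])
  list(X = X, geom = list(H = H, W = W, B = B))
}

# Full forward pass.  `training` enables dropout (rate `rate`); set
# `keep_cache` to retain everything the backward pass needs.
net_forward <- function(Xb, geom, params, config, training = FALSE,
                        rate = 0, keep_cache = FALSE) {
  act <- config$activation
  caches <- list()
  cur <- Xb; g <- geom
  for (i in seq_along(config$fire)) {
    fw <- tryCatch(
      fire_fwd(cur, list(sq_W = params[[sprintf("fire%d_sq_W", i)]],
                         sq_b = params[[sprintf("fire%d_sq_b", i)]],
                         e1_W = params[[sprintf("fire%d_e1_W", i)]],
                         e1_b = params[[sprintf("fire%d_e1_b", i)]],
                         e3_W = params[[sprintf("fire%d_e3_W", i)]],
                         e3_b = params[[sprintf("fire%d_e3_b", i)]]),
               g, act),
      error = function(e) stop("fire module ", i, ": ", conditionMessage(e)))
    caches[[sprintf("fire%d", i)]] <- if (keep_cache) fw$cache else NULL
    cur <- fw$out
  }
  mp <- maxpool_fwd(cur, config$pool_size, g)
  caches$pool <- if (keep_cache) mp$cache else NULL
  cur <- mp$out; g <- mp$geom

  tk <- tokenize_fwd(cur, config$patch_size, params$tok_W, params$tok_b,
                     params$pos, g)
  caches$tok <- if (keep_cache) tk$cache else NULL
  n_tok <- tk$n_tok
  cur <- tk$out

  dp <- dropout_fwd(cur, rate, training && "tokens" %in% config$dropout_sites)
  caches$drop_tok <- dp$mask
  cur <- dp$out

  for (j in seq_len(config$n_attention_blocks)) {
    pre <- sprintf("attn%d_", j)
    at <- attn_fwd(cur, list(Wq = params[[paste0(pre, "Wq")]],
                             Wk = params[[paste0(pre, "Wk")]],
                             Wv = params[[paste0(pre, "Wv")]],
                             Wo = params[[paste0(pre, "Wo")]],
                             bo = params[[paste0(pre, "bo")]]),
                   config$n_heads, n_tok, g$B)
    caches[[sprintf("attn%d", j)]] <- if (keep_cache) at$cache else NULL
    dp <- dropout_fwd(at$out, rate,
                      training && "attention" %in% config$dropout_sites)
    caches[[sprintf("drop_attn%d", j)]] <- dp$mask
    cur <- dp$out
  }

  # token grid back to a spatial map: token t at grid (ty, tx), row-major;
  # spatial index s = ty + (tx-1)*grid.  Reorder rows within each image.
  grid <- config$token_grid
  perm <- cache_get(paste("tokperm", grid), function() {
    t_of_s <- integer(grid * grid)
    for (ty in seq_len(grid)) for (tx in seq_len(grid)) {
      t_of_s[ty + (tx - 1L) * grid] <- (ty - 1L) * grid + tx
    }
    t_of_s
  })
  perm_glob <- as.integer(outer(perm, (seq_len(g$B) - 1L) * n_tok, "+"))
  cur <- cur[perm_glob, , drop = FALSE]
  g2 <- list(H = grid, W = grid, B = g$B)

  sp <- sep_fwd(cur, list(Wd = params$sep_Wd, bd = params$sep_bd,
                          Wp = params$sep_Wp, bp = params$sep_bp,
                          proj_W = params$sep_proj_W,
                          proj_b = params$sep_proj_b),
                g2, act)
  caches$sep <- if (keep_cache) sp$cache else NULL
  cur <- sp$out

  gp <- gap_fwd(cur, g2)
  caches$gap <- gp$cache
  dpg <- dropout_fwd(gp$out, rate,
                     training && "gap" %in% config$dropout_sites)
  caches$drop_gap <- dpg$mask

  hd <- head_fwd(dpg$out, params$fc_W, params$fc_b)
  caches$head <- if (keep_cache) hd$cache else NULL

  list(logits = hd$logits, probs = hd$probs, pred = hd$pred,
       caches = caches, geom_sep = g2, perm_glob = perm_glob,
       A_spatial = sp$A_spatial, n_tok = n_tok)
}

# Backward pass from d(logits); returns grads named like params.
net_backward <- function(dlogits, fwd, params, config) {
  caches <- fwd$caches
  gr <- list()
  hb <- head_bwd(dlogits, caches$head)
  gr$fc_W <- hb$dW; gr$fc_b <- hb$db
  dF <- dropout_bwd(hb$dF, caches$drop_gap)
  dcur <- gap_bwd(dF, caches$gap)

  sb <- sep_bwd(dcur, caches$sep)
  for (nm in names(sb$grads)) gr[[paste0("sep_", nm)]] <- sb$grads[[nm]]
  dcur <- sb$dX

  # invert the token-grid permutation
  dtok <- matrix(0, nrow(dcur), ncol(dcur))
  dtok[fwd$perm_glob, ] <- dcur

  for (j in rev(seq_len(config$n_attention_blocks))) {
    dtok <- dropout_bwd(dtok, caches[[sprintf("drop_attn%d", j)]])
    ab <- attn_bwd(dtok, caches[[sprintf("attn%d", j)]])
    pre <- sprintf("attn%d_", j)
    for (nm in names(ab$grads)) gr[[paste0(pre, nm)]] <- ab$grads[[nm]]
    dtok <- ab$dX
  }
  dtok <- dropout_bwd(dtok, caches$drop_tok)
  tb <- tokenize_bwd(dtok, caches$tok)
  gr$tok_W <- tb$dWe; gr$tok_b <- tb$dbe; gr$pos <- tb$dpos
  dcur <- maxpool_bwd(tb$dX, caches$pool)

  for (i in rev(seq_along(config$fire))) {
    fb <- fire_bwd(dcur, caches[[sprintf("fire%d", i)]])
    pre <- sprintf("fire%d_", i)
    for (nm in names(fb$grads)) gr[[paste0(pre, nm)]] <- fb$grads[[nm]]
    dcur <- fb$dX
  }
  gr
}

# ---------------------------------------------------------------------------
# Public single-image op wrappers (H x W x C arrays) for direct use and for
# oracle testing.

as_map <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  stopifnot(length(dim(x)) == 3L)
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  list(M = matrix(x, H * W, C), geom = list(H = H, W = W, B = 1L))
}

as_array <- function(M, geom) array(M, c(geom$H, geom$W, ncol(M)))

#' Fire module on a single feature map
#'
#' 1x1 squeeze convolution, activation, then parallel 1x1 and 3x3 expand
#' convolutions (zero-padded, stride 1), each activated and concatenated
#' along channels.  Output channels = `expand1 + expand3`; spatial size is
#' preserved.
#'
#' @param x `H x W x C` array (or `H x W` matrix).
#' @param weights list with `sq_W` (C x squeeze), `sq_b`, `e1_W`
#'   (squeeze x expand1), `e1_b`, `e3_W` ((9*squeeze) x expand3, kernels as
#'   column-major length-9 blocks per input channel), `e3_b`.
#' @param activation `"relu"` or `"identity"`.
#' @return `H x W x (expand1+expand3)` array.
#' @export
fire_module <- function(x, weights, activation = "relu") {
  m <- as_map(x)
  out <- fire_fwd(m$M, weights, m$geom, activation)$out
  as_array(out, m$geom)
}

#' Non-overlapping max pooling
#'
#' @param x `H x W x C` array (or matrix); `H`, `W` must be divisible by
#'   `pool_size` (no implicit padding).
#' @param pool_size window side.
#' @return Pooled `H/p x W/p x C` array.
#' @export
max_pool <- function(x, pool_size) {
  m <- as_map(x)
  r <- maxpool_fwd(m$M, as.integer(pool_size), m$geom)
  as_array(r$out, r$geom)
}

#' Patch tokenization with position encoding
#'
#' Splits the map into non-overlapping `patch_size` x `patch_size` patches
#' (row-major over the patch grid), flattens each (row-major within the
#' patch, channels blocked), applies the linear embedding and adds the
#' per-position encoding.
#'
#' @param x `H x W x C` array (or matrix).
#' @param patch_size patch side; `H`, `W` must divide evenly.
#' @param W_embed `(patch_size^2 * C) x d` embedding matrix.
#' @param b_embed length-`d` bias (default zeros).
#' @param pos `n_tokens x d` position encodings (default zeros).
#' @return `n_tokens x d` token matrix.
#' @export
tokenize <- function(x, patch_size, W_embed, b_embed = NULL, pos = NULL) {
  m <- as_map(x)
  d <- ncol(W_embed)
  n_tok <- (m$geom$H %/% patch_size) * (m$geom$W %/% patch_size)
  if (is.null(b_embed)) b_embed <- numeric(d)
  if (is.null(pos)) pos <- matrix(0, n_tok, d)
  tokenize_fwd(m$M, as.integer(patch_size), W_embed, b_embed, pos, m$geom)$out
}

#' Multi-head scaled dot-product self-attention
#'
#' Per head, `softmax(Q K^T / sqrt(key_dim)) V` with learned projections;
#' heads are concatenated, output-projected, and the input tokens are added
#' back (residual).  With `n_heads = 1` this is the single-head formulation.
#'
#' @param tokens `n x d` token matrix.
#' @param weights list with `Wq`, `Wk`, `Wv`, `Wo` (`d x d`) and `bo`
#'   (length `d`; defaults to zeros when absent).
#' @param n_heads number of heads (`d` must divide evenly).
#' @param residual add the input back (default TRUE, the standard block).
#' @return `n x d` matrix.
#' @export
attention <- function(tokens, weights, n_heads = 1L, residual = TRUE) {
  if (is.null(weights$bo)) weights$bo <- numeric(ncol(tokens))
  attn_fwd(tokens, weights, as.integer(n_heads), nrow(tokens), 1L,
           residual = residual)$out
}

#' Depthwise-separable residual block
#'
#' Per-channel 3x3 depthwise convolution (zero-padded) + activation, 1x1
#' pointwise channel mix + activation, then elementwise addition of the block
#' input (through a 1x1 projection when channel counts differ).
#'
#' @param x `H x W x C` array (or matrix).
#' @param weights list with `Wd` (9 x C, column-major kernels), `bd`, `Wp`
#'   (C x Cout), `bp`, and optionally `proj_W`/`proj_b`.
#' @param activation `"relu"` or `"identity"`.
#' @return `H x W x Cout` array.
#' @export
separable_residual_block <- function(x, weights, activation = "relu") {
  m <- as_map(x)
  out <- sep_fwd(m$M, weights, m$geom, activation)$out
  as_array(out, m$geom)
}

#' Global-average-pooling softmax head
#'
#' Spatial mean per channel, affine map `W x + b`, softmax, and argmax with
#' ties going to the lowest class index.
#'
#' @param x `H x W x C` array (or matrix).
#' @param W `n_classes x C` weight matrix.
#' @param b length-`n_classes` bias.
#' @return List with `pooled`, `probabilities`, `predicted_class` (1-based).
#' @export
gap_head <- function(x, W, b = NULL) {
  m <- as_map(x)
  if (is.null(b)) b <- numeric(nrow(W))
  F <- gap_fwd(m$M, m$geom)$out
  hd <- head_fwd(F, W, b)
  list(pooled = as.vector(F), probabilities = as.vector(hd$probs),
       predicted_class = hd$pred)
}
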