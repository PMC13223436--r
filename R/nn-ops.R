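# Network primitives: im2col/GEMM convolutions, max pooling, patch
# tokenization, multi-head self-attention, depthwise-separable convolution,
# global average pooling and the softmax head -- each with a hand-derived
# backward pass.  All heavy lifting is BLAS matrix products.
#
# Layout conventions
#   * a single feature map is an S x C matrix with S = H*W and spatial index
#     s = y + (x-1)*H (i.e. `as.vector()` of the H x W image matrix);
#   * a batch is a (B*S) x C matrix, image b in rows ((b-1)S+1):(bS);
#   * 3x3 kernels are passed as length-9 vectors in column-major kernel
#     order (`as.vector(K)` of the 3x3 matrix K, K[dy+2, dx+2]), stacked per
#     input channel: W3[(c-1)*9 + j, out_channel].
# Convolutions are cross-correlations with zero padding and stride 1, the
# deep-learning convention.

.geom_cache <- new.env(parent = emptyenv())

cache_get <- function(key, build) {
  v <- .geom_cache[[key]]
  if (is.null(v)) {
    v <- build()
    assign(key, v, envir = .geom_cache)
  }
  v
}

# Gather indices for k x k im2col over an H x W grid with zero padding.
im2col_idx <- function(H, W, k) {
  cache_get(paste("im2col", H, W, k), function() {
    p <- (k - 1L) %/% 2L
    Hp <- H + 2L * p; Wp <- W + 2L * p
    ys <- rep(seq_len(H), times = W)
    xs <- rep(seq_len(W), each = H)
    offs_dy <- rep(seq_len(k) - 1L - p, times = k)
    offs_dx <- rep(seq_len(k) - 1L - p, each = k)
    idx <- matrix(0L, H * W, k * k)
    for (j in seq_len(k * k)) {
      idx[, j] <- (ys + offs_dy[j] + p) + (xs + offs_dx[j] + p - 1L) * Hp
    }
    inner <- rep(seq_len(H), times = W) + p +
      (rep(seq_len(W), each = H) + p - 1L) * Hp
    list(idx_vec = as.integer(idx), k2 = k * k, Hp = Hp, Wp = Wp,
         inner = as.integer(inner))
  })
}

relu_fwd <- function(x) {
  m <- x > 0
  list(out = x * m, mask = m)
}
relu_bwd <- function(dout, mask) dout * mask

add_bias <- function(x, b) x + rep(b, each = nrow(x))

# --- convolution -----------------------------------------------------------

# Forward kxk convolution on a batched map (k = 1 or 3), with optionally
# fused bias+ReLU.  W: (k2*Cin) x Cout.  Both paths run through compiled
# kernels; the 3x3 im2col buffer is blocked per image (cache-resident) and
# rebuilt in the backward pass rather than cached.  The ReLU mask is
# recovered from the stored activations (out > 0).
conv_fwd <- function(Xb, W, b, k, geom, relu = FALSE) {
  Cin <- ncol(Xb)
  if (k == 1L) {
    if (nrow(W) != Cin) {
      stop("conv: input has ", Cin, " channels, weights expect ", nrow(W))
    }
    out <- conv1_fwd_cpp(Xb, W, as.numeric(b), relu)
    return(list(out = out,
                cache = list(k = 1L, Xb = Xb, W = W, out = out,
                             relu = relu)))
  }
  if (k != 3L) stop("conv: only 1x1 and 3x3 kernels are supported")
  if (nrow(W) != 9L * Cin) {
    stop("conv: input has ", Cin, " channels, weights expect ",
         nrow(W) / 9L)
  }
  out <- conv3_fwd_cpp(Xb, W, as.numeric(b), geom$H, geom$W, geom$B, relu)
  list(out = out, cache = list(k = 3L, Xb = Xb, W = W, geom = geom,
                               out = out, relu = relu))
}

conv_bwd <- function(dout, cache) {
  if (cache$k == 1L) {
    r <- conv1_bwd_cpp(cache$Xb, cache$W, dout, cache$out, cache$relu)
  } else {
    g <- cache$geom
    r <- conv3_bwd_cpp(cache$Xb, cache$W, dout, cache$out,
                       g$H, g$W, g$B, cache$relu)
  }
  list(dX = r$dX, dW = r$dW, db = as.numeric(r$db))
}

# --- fire module -----------------------------------------------------------

# weights: list(sq_W, sq_b, e1_W, e1_b, e3_W, e3_b).  The per-conv ReLUs are
# fused into the compiled kernels; their masks live in the cached outputs.
fire_fwd <- function(Xb, w, geom, act = "relu") {
  relu <- act == "relu"
  sq <- conv_fwd(Xb, w$sq_W, w$sq_b, 1L, geom, relu)
  e1 <- conv_fwd(sq$out, w$e1_W, w$e1_b, 1L, geom, relu)
  e3 <- conv_fwd(sq$out, w$e3_W, w$e3_b, 3L, geom, relu)
  out <- cbind(e1$out, e3$out)                   # channel concatenation
  list(out = out,
       cache = list(sq = sq$cache, e1 = e1$cache, e3 = e3$cache,
                    n1 = ncol(e1$out)))
}

fire_bwd <- function(dout, cache) {
  n1 <- cache$n1
  g1 <- conv_bwd(dout[, seq_len(n1), drop = FALSE], cache$e1)
  g3 <- conv_bwd(dout[, -seq_len(n1), drop = FALSE], cache$e3)
  gs <- conv_bwd(g1$dX + g3$dX, cache$sq)
  list(dX = gs$dX,
       grads = list(sq_W = gs$dW, sq_b = gs$db, e1_W = g1$dW, e1_b = g1$db,
                    e3_W = g3$dW, e3_b = g3$db))
}

# --- max pooling -----------------------------------------------------------

maxpool_fwd <- function(Xb, p, geom) {
  if (geom$H %% p != 0L || geom$W %% p != 0L) {
    stop("max_pool: dims ", geom$H, "x", geom$W,
         " not divisible by pool size ", p, " (no implicit padding)")
  }
  r <- maxpool_fwd_cpp(Xb, geom$H, geom$W, geom$B, as.integer(p))
  list(out = r$out,
       cache = list(arg = r$arg, n_in = nrow(Xb)),
       geom = list(H = geom$H %/% p, W = geom$W %/% p, B = geom$B))
}

maxpool_bwd <- function(dout, cache) {
  maxpool_bwd_cpp(dout, cache$arg, cache$n_in)
}

# --- patch tokenization ----------------------------------------------------

patch_idx <- function(H, W, P, B) {
  cache_get(paste("patch", H, W, P, B), function() {
    Ht <- H %/% P; Wt <- W %/% P
    n_tok <- Ht * Wt; P2 <- P * P; S <- H * W
    # token t (row-major over the token grid), within-patch q (row-major)
    idx <- integer(n_tok * P2)
    pos <- 0L
    for (ty in seq_len(Ht)) for (tx in seq_len(Wt)) {
      # token index t = (ty-1)*Wt + tx, filled in this loop order
      for (yy in seq_len(P)) for (xx in seq_len(P)) {
        pos <- pos + 1L
        y <- (ty - 1L) * P + yy; x <- (tx - 1L) * P + xx
        idx[pos] <- y + (x - 1L) * H
      }
    }
    # reorder so q is the fastest-varying dimension given loop order (t, q):
    # loop already yields q fastest within t.
    glob <- as.integer(outer(idx, (seq_len(B) - 1L) * S, "+"))
    list(idx_glob = glob, n_tok = n_tok, P2 = P2)
  })
}

# We: (P2*C) x d, be: d, pos: n_tok x d.
tokenize_fwd <- function(Xb, P, We, be, pos, geom) {
  if (geom$H %% P != 0L || geom$W %% P != 0L) {
    stop("tokenize: dims ", geom$H, "x", geom$W,
         " not divisible by patch size ", P)
  }
  C <- ncol(Xb)
  pi_ <- patch_idx(geom$H, geom$W, P, geom$B)
  A <- Xb[pi_$idx_glob, , drop = FALSE]   # rows ordered (q, t, b)
  arr <- array(A, c(pi_$P2, pi_$n_tok * geom$B, C))
  Xp <- matrix(aperm(arr, c(2, 1, 3)), pi_$n_tok * geom$B, pi_$P2 * C)
  tok <- add_bias(Xp %*% We, be)
  rep_t <- rep(seq_len(pi_$n_tok), geom$B)
  tok <- tok + pos[rep_t, , drop = FALSE]
  list(out = tok,
       cache = list(Xp = Xp, We = We, pi_ = pi_, geom = geom, C = C,
                    rep_t = rep_t, n_in = nrow(Xb)),
       n_tok = pi_$n_tok)
}

tokenize_bwd <- function(dtok, cache) {
  pi_ <- cache$pi_; geom <- cache$geom; C <- cache$C
  dWe <- crossprod(cache$Xp, dtok)
  dbe <- colSums(dtok)
  dpos <- rowsum(dtok, group = cache$rep_t)
  dXp <- dtok %*% t(cache$We)
  arr <- array(dXp, c(pi_$n_tok * geom$B, pi_$P2, C))
  dA <- matrix(aperm(arr, c(2, 1, 3)), pi_$n_tok * geom$B * pi_$P2, C)
  dX <- matrix(0, cache$n_in, C)
  dX[pi_$idx_glob, ] <- dA                 # patches partition the map
  list(dX = dX, dWe = dWe, dbe = dbe, dpos = dpos)
}

# --- self-attention --------------------------------------------------------

softmax_rows <- function(S) {
  m <- apply(S, 1L, max)
  E <- exp(S - m)
  E / rowSums(E)
}

# Tokens Tb: (B*n_tok) x d.  Per head: softmax(Q K^T / sqrt(dh)) V, heads
# concatenated, output-projected, plus residual.
attn_fwd <- function(Tb, w, n_heads, n_tok, B, residual = TRUE) {
  d <- ncol(Tb)
  if (d %% n_heads != 0L) stop("attention: embed_dim not divisible by n_heads")
  if (nrow(w$Wq) != d) stop("attention: projection dims do not match tokens")
  dh <- d %/% n_heads
  Q <- Tb %*% w$Wq; K <- Tb %*% w$Wk; V <- Tb %*% w$Wv
  O <- matrix(0, nrow(Tb), d)
  Amats <- vector("list", B * n_heads)
  sc <- 1 / sqrt(dh)
  for (bi in seq_len(B)) {
    rows <- ((bi - 1L) * n_tok + 1L):(bi * n_tok)
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      A <- softmax_rows(Q[rows, cols, drop = FALSE] %*%
                          t(K[rows, cols, drop = FALSE]) * sc)
      O[rows, cols] <- A %*% V[rows, cols, drop = FALSE]
      Amats[[(bi - 1L) * n_heads + h]] <- A
    }
  }
  Y <- add_bias(O %*% w$Wo, w$bo)
  if (residual) Y <- Y + Tb
  list(out = Y,
       cache = list(Tb = Tb, Q = Q, K = K, V = V, O = O, A = Amats, w = w,
                    n_heads = n_heads, n_tok = n_tok, B = B, dh = dh,
                    residual = residual))
}

attn_bwd <- function(dY, cache) {
  w <- cache$w; dh <- cache$dh; sc <- 1 / sqrt(dh)
  dWo <- crossprod(cache$O, dY)
  dbo <- colSums(dY)
  dO <- dY %*% t(w$Wo)
  dQ <- matrix(0, nrow(dY), ncol(dY))
  dK <- dQ; dV <- dQ
  for (bi in seq_len(cache$B)) {
    rows <- ((bi - 1L) * cache$n_tok + 1L):(bi * cache$n_tok)
    for (h in seq_len(cache$n_heads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      A <- cache$A[[(bi - 1L) * cache$n_heads + h]]
      dOh <- dO[rows, cols, drop = FALSE]
      Vh <- cache$V[rows, cols, drop = FALSE]
      dA <- dOh %*% t(Vh)
      dV[rows, cols] <- crossprod(A, dOh)
      dS <- A * (dA - rowSums(dA * A))
      dQ[rows, cols] <- dS %*% cache$K[rows, cols, drop = FALSE] * sc
      dK[rows, cols] <- crossprod(dS, cache$Q[rows, cols, drop = FALSE]) * sc
    }
  }
  dT <- dQ %*% t(w$Wq) + dK %*% t(w$Wk) + dV %*% t(w$Wv)
  if (cache$residual) dT <- dT + dY
  list(dX = dT,
       grads = list(Wq = crossprod(cache$Tb, dQ),
                    Wk = crossprod(cache$Tb, dK),
                    Wv = crossprod(cache$Tb, dV),
                    Wo = dWo, bo = dbo))
}

# --- depthwise separable residual block -------------------------------------

# Wd: 9 x C (per-channel 3x3 kernels), bd: C; Wp: C x Cout, bp: Cout;
# optional proj: C x Cout 1x1 on the residual branch when channels differ.
sep_fwd <- function(Xb, w, geom, act = "relu") {
  C <- ncol(Xb)
  if (ncol(w$Wd) != C) stop("separable block: channel mismatch (", C, " vs ",
                            ncol(w$Wd), ")")
  ii <- im2col_idx(geom$H, geom$W, 3L)
  S <- geom$H * geom$W
  A3 <- array(0, c(S, 9L, geom$B, C))
  xp <- matrix(0, ii$Hp * ii$Wp, C)
  for (bi in seq_len(geom$B)) {
    rows <- ((bi - 1L) * S + 1L):(bi * S)
    xp[ii$inner, ] <- Xb[rows, , drop = FALSE]
    A3[, , bi, ] <- array(xp[ii$idx_vec, , drop = FALSE], c(S, 9L, C))
  }
  dw <- matrix(0, geom$B * S, C)
  for (j in 1:9) {
    slice <- matrix(aperm(A3[, j, , , drop = FALSE], c(1, 3, 4, 2)),
                    S * geom$B, C)
    dw <- dw + slice * rep(w$Wd[j, ], each = S * geom$B)
  }
  dw <- add_bias(dw, w$bd)
  a1 <- if (act == "relu") relu_fwd(dw) else list(out = dw, mask = NULL)
  pw <- add_bias(a1$out %*% w$Wp, w$bp)
  a2 <- if (act == "relu") relu_fwd(pw) else list(out = pw, mask = NULL)
  res <- Xb
  proj <- NULL
  if (ncol(a2$out) != C) {
    if (is.null(w$proj_W)) {
      stop("separable block: residual channels ", C, " != output ",
           ncol(a2$out), " and no projection provided")
    }
    pj <- conv_fwd(Xb, w$proj_W, w$proj_b, 1L, geom)
    res <- pj$out
    proj <- pj$cache
  }
  out <- a2$out + res
  list(out = out,
       cache = list(A3 = A3, m1 = a1$mask, m2 = a2$mask, a1 = a1$out,
                    Xb = Xb, w = w, geom = geom, ii = ii, C = C,
                    proj = proj, act = act),
       A_spatial = a2$out)   # post-activation pointwise map (Grad-CAM layer)
}

sep_bwd <- function(dout, cache) {
  w <- cache$w; geom <- cache$geom; ii <- cache$ii
  S <- geom$H * geom$W
  dres <- dout
  grads <- list()
  if (!is.null(cache$proj)) {
    gp <- conv_bwd(dout, cache$proj)
    grads$proj_W <- gp$dW; grads$proj_b <- gp$db
    dX_res <- gp$dX
  } else {
    dX_res <- dout
  }
  d2 <- if (cache$act == "relu") relu_bwd(dout, cache$m2) else dout
  grads$Wp <- crossprod(cache$a1, d2)
  grads$bp <- colSums(d2)
  ddw <- d2 %*% t(w$Wp)
  d1 <- if (cache$act == "relu") relu_bwd(ddw, cache$m1) else ddw
  grads$bd <- colSums(d1)
  dWd <- matrix(0, 9L, cache$C)
  dX <- matrix(0, nrow(dout), cache$C)
  for (bi in seq_len(geom$B)) {
    rows <- ((bi - 1L) * S + 1L):(bi * S)
    d1b <- d1[rows, , drop = FALSE]
    A3b <- array(cache$A3[, , bi, ], c(S, 9L, cache$C))
    dAb <- matrix(0, S * 9L, cache$C)
    for (j in 1:9) {
      dWd[j, ] <- dWd[j, ] + colSums(d1b * A3b[, j, ])
      # route the gradient back through the im2col gather for offset j
      dAb[((j - 1L) * S + 1L):(j * S), ] <- d1b * rep(w$Wd[j, ], each = S)
    }
    rs <- rowsum(dAb, group = ii$idx_vec)
    dxp <- matrix(0, ii$Hp * ii$Wp, cache$C)
    dxp[as.integer(rownames(rs)), ] <- rs
    dX[rows, ] <- dxp[ii$inner, , drop = FALSE]
  }
  grads$Wd <- dWd
  list(dX = dX + dX_res, grads = grads)
}

# --- global average pooling + fully-connected softmax head ------------------

gap_fwd <- function(Xb, geom) {
  S <- geom$H * geom$W
  grp <- rep(seq_len(geom$B), each = S)
  F <- rowsum(Xb, group = grp) / S
  list(out = F, cache = list(S = S, B = geom$B, n_in = nrow(Xb)))
}

gap_bwd <- function(dF, cache) {
  dF[rep(seq_len(cache$B), each = cache$S), , drop = FALSE] / cache$S
}

# Wfc: K x C (row per class), bfc: K.
head_fwd <- function(F, Wfc, bfc) {
  if (ncol(F) != ncol(Wfc)) {
    stop("head: feature dim ", ncol(F), " != weight dim ", ncol(Wfc))
  }
  logits <- add_bias(F %*% t(Wfc), bfc)
  probs <- softmax_rows(logits)
  list(logits = logits, probs = probs,
       pred = max.col(probs, ties.method = "first"),
       cache = list(F = F, Wfc = Wfc))
}

head_bwd <- function(dlogits, cache) {
  list(dF = dlogits %*% cache$Wfc,
       dW = crossprod(dlogits, cache$F),
       db = colSums(dlogits))
}

# Inverted dropout on a batched matrix; draws from the current RNG.
dropout_fwd <- function(Xb, rate, training) {
  if (!training || rate <= 0) return(list(out = Xb, mask = NULL))
  keep <- 1 - rate
  mask <- (matrix(stats::runif(length(Xb)), nrow(Xb)) < keep) / keep
  list(out = Xb * mask, mask = mask)
}
dropout_bwd <- function(dout, mask) {
  if (is.null(mask)) dout else dout * mask
}

cross_entropy <- function(probs, y_idx) {
  p <- pmax(probs[cbind(seq_len(nrow(probs)), y_idx)], 1e-12)
  -mean(log(p))
}
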