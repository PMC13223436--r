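# Independent brute-force oracles used to check the vectorized/compiled ops.
# These are deliberately naive (nested loops, direct definitions) and share
# no code with the implementation beyond the documented conventions.

# Cross-correlation with zero padding, stride 1.  x: H x W x Cin array;
# kernels: list over output channels, each a list over input channels of
# k x k matrices; bias: length Cout.  Returns H x W x Cout.
oracle_conv <- function(x, kernels, bias, act = identity) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]
  Cout <- length(kernels)
  k <- nrow(kernels[[1]][[1]])
  p <- (k - 1) %/% 2
  out <- array(0, c(H, W, Cout))
  for (o in seq_len(Cout)) {
    for (y in 1:H) for (xx in 1:W) {
      acc <- bias[o]
      for (c in seq_len(Cin)) {
        K <- kernels[[o]][[c]]
        for (dy in -p:p) for (dx in -p:p) {
          yy <- y + dy; xc <- xx + dx
          v <- if (yy >= 1 && yy <= H && xc >= 1 && xc <= W) x[yy, xc, c] else 0
          acc <- acc + K[dy + p + 1, dx + p + 1] * v
        }
      }
      out[y, xx, o] <- act(acc)
    }
  }
  out
}

# Convert a (9*Cin) x Cout packed weight matrix (column-major kernels per
# input channel) into the oracle's list-of-kernels form.
unpack_w3 <- function(W3, Cin) {
  lapply(seq_len(ncol(W3)), function(o) {
    lapply(seq_len(Cin), function(c) {
      matrix(W3[(c - 1) * 9 + 1:9, o], 3, 3)
    })
  })
}

# Exhaustive window-max pooling oracle on an H x W x C array.
oracle_pool <- function(x, p) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  out <- array(0, c(H / p, W / p, C))
  for (c in seq_len(C)) {
    for (y in seq_len(H / p)) for (xx in seq_len(W / p)) {
      out[y, xx, c] <- max(x[((y - 1) * p + 1):(y * p),
                             ((xx - 1) * p + 1):(xx * p), c])
    }
  }
  out
}

# Single-head scaled dot-product attention, written directly from the
# definition (no residual, identity projections assumed by the caller).
oracle_attention <- function(tokens, key_dim) {
  n <- nrow(tokens)
  S <- tokens %*% t(tokens) / sqrt(key_dim)
  A <- t(apply(S, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  A %*% tokens
}

# Exhaustive per-sample counting oracle for classification metrics.
oracle_report <- function(true, pred, classes) {
  per <- lapply(classes, function(cl) {
    tp <- sum(true == cl & pred == cl)
    fp <- sum(true != cl & pred == cl)
    fn <- sum(true == cl & pred != cl)
    tn <- sum(true != cl & pred != cl)
    pr <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rc <- if (tp + fn == 0) 0 else tp / (tp + fn)
    sp <- if (tn + fp == 0) 0 else tn / (tn + fp)
    f1 <- if (pr + rc == 0) 0 else 2 * pr * rc / (pr + rc)
    c(precision = pr, recall = rc, specificity = sp, f1 = f1)
  })
  m <- do.call(rbind, per)
  list(per_class = m,
       macro = colMeans(m),
       accuracy = mean(true == pred))
}

# Pairwise-concordance AUC oracle, ties counted 1/2.
oracle_auc <- function(scores, is_pos) {
  pos <- scores[is_pos]; neg <- scores[!is_pos]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Connected components (4-neighbour flood fill) of a logical matrix; returns
# the number of components with at least `min_px` pixels.
count_blobs <- function(mask, min_px = 4L) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nblob <- 0L
  for (y0 in seq_len(H)) for (x0 in seq_len(W)) {
    if (!mask[y0, x0] || lab[y0, x0] != 0L) next
    nblob <- nblob + 1L
    size <- 0L
    queue <- list(c(y0, x0))
    lab[y0, x0] <- nblob
    while (length(queue)) {
      pt <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      size <- size + 1L
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        y <- pt[1] + d[1]; x <- pt[2] + d[2]
        if (y >= 1 && y <= H && x >= 1 && x <= W &&
            mask[y, x] && lab[y, x] == 0L) {
          lab[y, x] <- nblob
          queue[[length(queue) + 1L]] <- c(y, x)
        }
      }
    }
    if (size < min_px) nblob <- nblob - 1L  # too small: not counted
  }
  nblob
}

# Two handcrafted image features for the class-separability oracle:
# mean intensity over the lung fields, and the count of bright blobs inside
# them (thresholded well above the lung base so noise pixels are rare).
stump_features <- function(image) {
  lung <- synth_lung_mask(nrow(image))
  thr <- image > 0.45 & lung
  c(mean_lung = mean(image[lung]), blobs = count_blobs(thr, min_px = 2L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive depth-2 decision tree (root split + one optional split per
# child, majority-label leaves) over two features.  Unlike greedy CART this
# optimizes holdout-style accuracy over the whole depth-2 family, which is
# what "a depth-2 stump separates the classes" asserts.
fit_depth2_stump <- function(X, y) {
  y <- as.factor(y)
  thr_cand <- lapply(seq_len(ncol(X)), function(j) {
    v <- sort(unique(X[, j]))
    if (length(v) > 24) {
      v <- sort(unique(stats::quantile(v, seq(0.02, 0.98, length.out = 24))))
    }
    if (length(v) < 2) numeric(0) else (v[-1] + v[-length(v)]) / 2
  })
  majority <- function(idx) {
    if (!length(idx)) return(levels(y)[1])
    names(which.max(table(y[idx])))
  }
  n_maj <- function(idx) if (!length(idx)) 0L else max(table(y[idx]))
  # best single split of a subset; returns count correct and the rule
  best_leaf_split <- function(idx) {
    best <- list(correct = n_maj(idx), j = NA, t = NA,
                 labL = majority(idx), labR = majority(idx))
    for (j in seq_along(thr_cand)) for (t in thr_cand[[j]]) {
      L <- idx[X[idx, j] <= t]
      R <- idx[X[idx, j] > t]
      cc <- n_maj(L) + n_maj(R)
      if (cc > best$correct) {
        best <- list(correct = cc, j = j, t = t,
                     labL = majority(L), labR = majority(R))
      }
    }
    best
  }
  best <- NULL
  for (j in seq_along(thr_cand)) for (t in thr_cand[[j]]) {
    L <- which(X[, j] <= t)
    R <- which(X[, j] > t)
    bl <- best_leaf_split(L)
    br <- best_leaf_split(R)
    tot <- bl$correct + br$correct
    if (is.null(best) || tot > best$tot) {
      best <- list(tot = tot, j = j, t = t, left = bl, right = br)
    }
  }
  structure(best, class = "depth2_stump")
}

predict_depth2_stump <- function(fit, X) {
  leaf <- function(node, x) {
    if (is.na(node$j)) return(node$labL)
    if (x[node$j] <= node$t) node$labL else node$labR
  }
  apply(X, 1L, function(x) {
    node <- if (x[fit$j] <= fit$t) fit$left else fit$right
    leaf(node, x)
  })
}
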