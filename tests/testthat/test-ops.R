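# Network primitives against brute-force oracles and hand-computed values.

make_fire_weights <- function(cin, sq, e1, e3, seed = 1L) {
  with_seed(seed, list(
    sq_W = matrix(stats::rnorm(cin * sq), cin, sq),
    sq_b = stats::rnorm(sq),
    e1_W = matrix(stats::rnorm(sq * e1), sq, e1),
    e1_b = stats::rnorm(e1),
    e3_W = matrix(stats::rnorm(9 * sq * e3), 9 * sq, e3),
    e3_b = stats::rnorm(e3)))
}

test_that("fire module: channel concat arithmetic and zero weights", {
  x <- array(with_seed(1L, stats::runif(6 * 6 * 3)), c(6, 6, 3))
  w <- make_fire_weights(3, 2, 4, 8)
  out <- fire_module(x, w)
  expect_identical(dim(out), c(6L, 6L, 12L))     # expand1 + expand3
  wz <- lapply(w, function(m) m * 0)
  expect_equal(fire_module(x, wz), array(0, c(6, 6, 12)))
  # channel mismatch is a named error
  expect_error(fire_module(array(0, c(6, 6, 2)), w), "channels")
})

test_that("fire module: hand-computed 2x2 example", {
  x <- rbind(c(1, 2), c(3, 4))
  w <- list(sq_W = matrix(2), sq_b = 0,
            e1_W = matrix(1), e1_b = 0,
            e3_W = matrix(0, 9, 1), e3_b = 0)
  out <- fire_module(x, w)
  expect_equal(out[, , 1], rbind(c(2, 4), c(6, 8)))
  expect_equal(out[, , 2], matrix(0, 2, 2))
})

test_that("fire module matches the brute-force convolution oracle", {
  relu <- function(v) pmax(v, 0)
  for (seed in 1:3) {
    x <- array(with_seed(seed, stats::rnorm(8 * 8 * 2)), c(8, 8, 2))
    w <- make_fire_weights(2, 3, 4, 5, seed = seed + 10L)
    got <- fire_module(x, w)
    # oracle: squeeze (1x1) -> relu -> parallel 1x1 / 3x3 -> relu -> concat
    sq_k <- lapply(seq_len(3), function(o) {
      lapply(seq_len(2), function(c) matrix(w$sq_W[c, o], 1, 1))
    })
    mid <- oracle_conv(x, sq_k, w$sq_b, act = relu)
    e1_k <- lapply(seq_len(4), function(o) {
      lapply(seq_len(3), function(c) matrix(w$e1_W[c, o], 1, 1))
    })
    o1 <- oracle_conv(mid, e1_k, w$e1_b, act = relu)
    o3 <- oracle_conv(mid, unpack_w3(w$e3_W, 3), w$e3_b, act = relu)
    want <- array(c(o1, o3), c(8, 8, 9))
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("max pooling: hand examples, oracle equivalence, divisibility", {
  expect_equal(max_pool(rbind(c(1, 2), c(3, 4)), 2)[1, 1, 1], 4)
  expect_equal(max_pool(matrix(0.3, 4, 4), 2), array(0.3, c(2, 2, 1)))
  x <- array(with_seed(9L, stats::rnorm(4 * 4 * 3)), c(4, 4, 3))
  expect_equal(max_pool(x, 2), oracle_pool(x, 2))
  expect_error(max_pool(matrix(0, 5, 5), 2), "divisible")
})

test_that("tokenization: token count, position fallback, patch extraction", {
  x <- matrix(with_seed(2L, stats::runif(64)), 8, 8)
  d <- 16L
  We0 <- matrix(0, 16, d)
  pos <- matrix(with_seed(3L, stats::rnorm(4 * d)), 4, d)
  tok <- tokenize(x, 4L, We0, pos = pos)
  expect_identical(dim(tok), c(4L, 16L))         # (8/4)^2 tokens
  expect_equal(tok, pos)                         # zero embedding -> encodings
  # identity embedding, zero encodings: token k is flattened patch k
  x2 <- matrix(with_seed(4L, stats::rnorm(16)), 4, 4)
  tok2 <- tokenize(x2, 2L, diag(4))
  # token order row-major over the grid; within-patch row-major
  patch <- function(ty, tx) {
    p <- x2[(ty - 1) * 2 + 1:2, (tx - 1) * 2 + 1:2]
    as.vector(t(p))
  }
  want <- rbind(patch(1, 1), patch(1, 2), patch(2, 1), patch(2, 2))
  expect_equal(tok2, want, ignore_attr = TRUE)
  expect_error(tokenize(matrix(0, 5, 5), 2L, diag(4)), "divisible")
})

test_that("attention: degenerate cases and hand-computed softmax weights", {
  idw <- list(Wq = diag(1), Wk = diag(1), Wv = diag(1), Wo = diag(1))
  # single token: softmax over one score is 1
  one <- matrix(2.5, 1, 1)
  expect_equal(attention(one, idw, residual = FALSE), one)
  # two tokens with values 1, 0: weights e/(e+1), 1/(e+1)
  toks <- matrix(c(1, 0), 2, 1)
  got <- attention(toks, idw, residual = FALSE)
  expect_equal(got[1, 1], exp(1) / (exp(1) + 1), tolerance = 1e-10)
  expect_equal(got[2, 1], 0.5, tolerance = 1e-10)
  # identical tokens give identical outputs (with residual)
  d <- 8L
  w <- with_seed(5L, list(Wq = matrix(stats::rnorm(64), d), Wk = matrix(stats::rnorm(64), d),
                          Wv = matrix(stats::rnorm(64), d), Wo = matrix(stats::rnorm(64), d)))
  same <- matrix(rep(stats::rnorm(d), each = 5), 5, d)
  out <- attention(same, w, n_heads = 2L)
  expect_lt(max(apply(out, 2, stats::sd)), 1e-12)
  expect_error(attention(same, list(Wq = diag(4), Wk = diag(4),
                                    Wv = diag(4), Wo = diag(4))), "match")
})

test_that("attention with identity projections matches the definition oracle", {
  toks <- matrix(with_seed(6L, stats::rnorm(12)), 4, 3)
  idw <- list(Wq = diag(3), Wk = diag(3), Wv = diag(3), Wo = diag(3))
  got <- attention(toks, idw, n_heads = 1L, residual = FALSE)
  expect_equal(got, oracle_attention(toks, key_dim = 3), tolerance = 1e-12)
})

test_that("attention softmax rows sum to one for every head and token", {
  pn <- asNamespace("pneumonet")
  toks <- matrix(with_seed(7L, stats::rnorm(6 * 8)), 6, 8)
  w <- with_seed(8L, list(Wq = matrix(stats::rnorm(64), 8), Wk = matrix(stats::rnorm(64), 8),
                          Wv = matrix(stats::rnorm(64), 8), Wo = matrix(stats::rnorm(64), 8),
                          bo = numeric(8)))
  fw <- pn$attn_fwd(toks, w, n_heads = 4L, n_tok = 6L, B = 1L)
  for (A in fw$cache$A) expect_equal(rowSums(A), rep(1, 6), tolerance = 1e-12)
})

test_that("separable residual block: identity paths and oracle equivalence", {
  x <- array(with_seed(10L, stats::rnorm(3 * 3 * 2)), c(3, 3, 2))
  # all conv weights zero + ReLU: pure residual path
  wz <- list(Wd = matrix(0, 9, 2), bd = numeric(2),
             Wp = matrix(0, 2, 2), bp = numeric(2))
  expect_equal(separable_residual_block(x, wz), x)
  # identity depthwise + identity pointwise, identity activation: 2x input
  idk <- rep(0, 9); idk[5] <- 1                  # center tap of the 3x3 kernel
  wi <- list(Wd = matrix(idk, 9, 2), bd = numeric(2),
             Wp = diag(2), bp = numeric(2))
  expect_equal(separable_residual_block(x, wi, activation = "identity"),
               2 * x)
  # seeded weights against composed per-channel conv + channel mix oracle
  w <- with_seed(11L, list(Wd = matrix(stats::rnorm(18), 9, 2), bd = stats::rnorm(2),
                           Wp = matrix(stats::rnorm(4), 2, 2), bp = stats::rnorm(2)))
  got <- separable_residual_block(x, w)
  relu <- function(v) pmax(v, 0)
  dk <- lapply(1:2, function(o) {
    lapply(1:2, function(c) {
      if (c == o) matrix(w$Wd[, c], 3, 3) else matrix(0, 3, 3)
    })
  })
  dw <- oracle_conv(x, dk, w$bd, act = relu)
  pk <- lapply(1:2, function(o) lapply(1:2, function(c) matrix(w$Wp[c, o], 1, 1)))
  pw <- oracle_conv(dw, pk, w$bp, act = relu)
  expect_equal(got, pw + x, tolerance = 1e-6)
})

test_that("GAP head: pooled means, uniform softmax tie rule, hand softmax", {
  x <- array(0, c(2, 2, 1))
  x[, , 1] <- rbind(c(1, 2), c(3, 4))
  h <- gap_head(x, W = matrix(0, 4, 1), b = numeric(4))
  expect_equal(h$pooled, 2.5)
  expect_equal(h$probabilities, rep(0.25, 4))
  expect_identical(h$predicted_class, 1L)        # ties: lowest index
  # logits (2, 0) via bias on a zero feature
  h2 <- gap_head(array(0, c(2, 2, 1)), W = matrix(0, 2, 1), b = c(2, 0))
  expect_equal(h2$probabilities,
               c(exp(2), 1) / (exp(2) + 1), tolerance = 1e-10)
  expect_error(gap_head(array(0, c(2, 2, 3)), W = matrix(0, 2, 1)), "dim")
})

test_that("the full forward pass equals the hand-composed chain of public ops", {
  cfg <- net_config(input_size = 32L,
                    fire = list(list(squeeze = 4L, expand1 = 8L,
                                     expand3 = 8L)),
                    pool_size = 2L, patch_size = 4L, embed_dim = 16L,
                    n_heads = 2L, n_attention_blocks = 1L,
                    sep_channels = 16L, n_classes = 4L)
  params <- net_init(cfg, seed = 3L)
  img <- matrix(with_seed(4L, stats::rnorm(32 * 32)), 32, 32)
  pn <- asNamespace("pneumonet")
  st <- pn$stack_images(list(img))
  fw <- pn$net_forward(st$X, st$geom, params, cfg, training = FALSE, rate = 0)

  x <- fire_module(img, list(sq_W = params$fire1_sq_W,
                             sq_b = params$fire1_sq_b,
                             e1_W = params$fire1_e1_W,
                             e1_b = params$fire1_e1_b,
                             e3_W = params$fire1_e3_W,
                             e3_b = params$fire1_e3_b))
  x <- max_pool(x, 2L)
  tok <- tokenize(x, 4L, params$tok_W, params$tok_b, params$pos)
  tok <- attention(tok, list(Wq = params$attn1_Wq, Wk = params$attn1_Wk,
                             Wv = params$attn1_Wv, Wo = params$attn1_Wo,
                             bo = params$attn1_bo), n_heads = 2L)
  grid <- cfg$token_grid
  map <- array(0, c(grid, grid, cfg$embed_dim))
  for (ty in seq_len(grid)) for (tx in seq_len(grid)) {
    map[ty, tx, ] <- tok[(ty - 1L) * grid + tx, ]   # row-major token order
  }
  x <- separable_residual_block(map, list(Wd = params$sep_Wd,
                                          bd = params$sep_bd,
                                          Wp = params$sep_Wp,
                                          bp = params$sep_bp))
  h <- gap_head(x, params$fc_W, params$fc_b)
  expect_equal(as.vector(fw$probs), h$probabilities, tolerance = 1e-10)
  expect_equal(sum(fw$probs), 1, tolerance = 1e-6)
  expect_identical(fw$pred, h$predicted_class)
})
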