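# Training machinery: stratified folds, determinism, leakage, dropout
# bookkeeping.  Model runs use a deliberately small configuration.

tiny_cfg <- function() {
  net_config(input_size = 32L,
             fire = list(list(squeeze = 4L, expand1 = 8L, expand3 = 8L)),
             pool_size = 2L, patch_size = 4L, embed_dim = 16L, n_heads = 2L,
             n_attention_blocks = 1L, sep_channels = 16L, n_classes = 4L)
}

tiny_data <- function(n = 10L, seed = 1L) {
  synth_dataset(synth_spec(n_per_class = n, image_size = 32L, seed = seed))
}

test_that("stratified folds balance every class to within one sample", {
  y <- rep(c("a", "b", "c", "d"), each = 25L)
  f <- stratified_kfold(y, 5L, seed = 3L)
  expect_true(all(table(f) == 20L))
  expect_true(all(table(y, f) == 5L))
  # folds partition the data
  expect_identical(sort(unique(f)), 1:5)
  expect_length(f, 100L)
  # round-robin remainder: 26 members over 5 folds -> sizes 6,5,5,5,5
  f2 <- stratified_kfold(rep("a", 26L), 5L, seed = 1L)
  expect_identical(sort(as.integer(table(f2)), decreasing = TRUE),
                   c(6L, 5L, 5L, 5L, 5L))
  expect_error(stratified_kfold(c("a", "a", "b"), 2L, 1L), "'b'")
})

test_that("training is deterministic given the seed", {
  ds <- tiny_data()
  ctrl <- train_control(max_epochs = 2L, batch_size = 16L, seed = 7L)
  f1 <- pneumonet(ds, config = tiny_cfg(), control = ctrl, val = 0.2)
  f2 <- pneumonet(ds, config = tiny_cfg(), control = ctrl, val = 0.2)
  expect_identical(f1$history, f2$history)
  expect_identical(coef(f1), coef(f2))
})

test_that("validation images never influence normalization or weights", {
  ds <- tiny_data()
  vi <- c(1:2, 11:12, 21:22, 31:32)   # two images per class
  tr_x <- ds$images[-vi]
  tr_y <- ds$labels[-vi]
  va1 <- list(x = ds$images[vi], y = ds$labels[vi])
  va2 <- list(x = lapply(ds$images[vi], function(m) 1 - m),
              y = ds$labels[vi])
  ctrl <- train_control(max_epochs = 1L, batch_size = 16L, seed = 5L)
  f1 <- pneumonet(tr_x, tr_y, tiny_cfg(), ctrl, val = va1)
  f2 <- pneumonet(tr_x, tr_y, tiny_cfg(), ctrl, val = va2)
  expect_identical(f1$stats, f2$stats)
  expect_identical(coef(f1), coef(f2))
})

test_that("fixed-dropout training logs a constant rate within bounds", {
  ds <- tiny_data()
  ctrl <- train_control(max_epochs = 2L, batch_size = 16L, seed = 2L,
                        fixed_dropout = 0.4)
  fit <- pneumonet(ds, config = tiny_cfg(), control = ctrl, val = 0.2)
  expect_true(all(fit$history$dropout_rate == 0.4))
  expect_lte(nrow(fit$history), ctrl$max_epochs)
})

test_that("adaptive dropout scheduling keeps every rate within bounds", {
  ds <- tiny_data(6L)
  sc <- dropout_search_control(pop_size = 4L, max_iters = 2L,
                               eval_budget = 1L, seed = 1L)
  ctrl <- train_control(max_epochs = 2L, batch_size = 8L, seed = 4L,
                        dropout_search = TRUE, search_control = sc,
                        search_interval = 1L, search_val_cap = 8L)
  fit <- pneumonet(ds, config = tiny_cfg(), control = ctrl, val = 0.25)
  expect_true(all(fit$history$dropout_rate >= 0.1 &
                  fit$history$dropout_rate <= 0.6))
  expect_true(all(fit$dropout_trace$rate >= 0.1 &
                  fit$dropout_trace$rate <= 0.6))
  expect_true(all(c("round", "iteration", "rate", "fitness", "phase") %in%
                  names(fit$dropout_trace)))
})

test_that("set_dropout enforces the configured bounds", {
  ds <- tiny_data(6L)
  ctrl <- train_control(max_epochs = 1L, batch_size = 8L, seed = 9L)
  fit <- pneumonet(ds, config = tiny_cfg(), control = ctrl, val = 0.25)
  fit2 <- set_dropout(fit, 0.6)
  expect_equal(fit2$dropout_rate, 0.6)
  expect_error(set_dropout(fit, 0.95), "0.6")
  # evaluation-mode predictions ignore the dropout rate entirely
  p1 <- predict(fit, ds$images[1:4])
  p2 <- predict(fit2, ds$images[1:4])
  expect_identical(p1, p2)
})

test_that("cross-validation produces k fold reports and an aggregate", {
  ds <- tiny_data(6L)
  ctrl <- train_control(max_epochs = 1L, batch_size = 8L, seed = 3L,
                        k_folds = 3L)
  cv <- pneumonet_cv(ds, config = tiny_cfg(), control = ctrl)
  expect_equal(nrow(cv$fold_metrics), 3L)
  expect_true(all(table(cv$folds) == 8L))
  expect_named(cv$aggregate, c("mean", "sd"))
  expect_true(all(cv$fold_metrics$accuracy >= 0 &
                  cv$fold_metrics$accuracy <= 1))
})

test_that("simulate and residuals methods are consistent with probabilities", {
  ds <- tiny_data(6L)
  ctrl <- train_control(max_epochs = 1L, batch_size = 8L, seed = 6L)
  fit <- pneumonet(ds, config = tiny_cfg(), control = ctrl, val = 0.25)
  sims <- simulate(fit, nsim = 3L, seed = 1L)
  expect_equal(dim(sims), c(nrow(fit$val$probs), 3L))
  expect_true(all(unlist(lapply(sims, levels)) %in% fit$classes))
  r <- residuals(fit)
  expect_equal(dim(r), dim(fit$val$probs))
  expect_true(all(abs(rowSums(r)) < 1e-9))   # one-hot minus probs sums to 0
})
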