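# Shared experiment fixtures for the end-to-end tests.  The heavyweight
# trained models are built lazily, once per test run, and reused by several
# test blocks (full-task training takes minutes on one CPU).

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(.fixtures[[name]])) assign(name, build(), envir = .fixtures)
  .fixtures[[name]]
}

# The synthetic study conditions: 4 classes x 200 X-ray-like images, 64x64,
# severity 1, noise 0.05, with a 15% stratified test holdout.
e2e_data <- function(seed = 1L) {
  memo(paste0("data", seed), function() {
    ds <- synth_dataset(synth_spec(n_per_class = 200L, image_size = 64L,
                                   severity = 1, noise_sd = 0.05,
                                   seed = seed))
    ti <- stratified_holdout(ds$labels, 0.15,
                                         hash_seed(seed, "test"))
    list(ds = ds, test_idx = ti)
  })
}

# Desk-scale training settings (see the methods vignette): learning rate
# 1e-3 from a small grid search, <= 30 epochs with early stopping.
e2e_control <- function(seed = 1L, max_epochs = 30L, ...) {
  train_control(max_epochs = max_epochs, learning_rate = 1e-3, seed = seed,
                ...)
}

# Fixed-dropout-0.5 model on the synthetic task: used by the end-to-end
# learning, saliency-localization, and dropout-comparison tests.
fixed_fit <- function(seed = 1L) {
  memo(paste0("fixed", seed), function() {
    d <- e2e_data(seed)
    fit <- pneumonet(d$ds$images[-d$test_idx], d$ds$labels[-d$test_idx],
                     net_config(), e2e_control(seed), val = 0.15)
    pred <- predict(fit, d$ds$images[d$test_idx], type = "class")
    list(fit = fit, test_acc = mean(pred == d$ds$labels[d$test_idx]))
  })
}

# Adaptive-dropout arm: identical task and seed, search rounds every 5
# epochs (population 10, 6 iterations, 1 batch per candidate evaluation).
search_fit <- function(seed = 1L) {
  memo(paste0("search", seed), function() {
    d <- e2e_data(seed)
    ctrl <- e2e_control(
      seed,
      max_epochs = 20L,
      dropout_search = TRUE,
      search_control = dropout_search_control(pop_size = 10L, max_iters = 6L,
                                              eval_budget = 1L),
      search_interval = 5L, search_val_cap = 64L)
    pneumonet(d$ds$images[-d$test_idx], d$ds$labels[-d$test_idx],
              net_config(), ctrl, val = 0.15)
  })
}

# Fixed-dropout baseline matched to the adaptive arm's epoch budget: epoch
# seeding is per-epoch, so the first 12 epochs of the 30-epoch fixed run are
# identical to a 12-epoch run; its history row 12 IS the matched baseline.
fixed_val_f1_at <- function(epoch, seed = 1L) {
  h <- fixed_fit(seed)$fit$history
  h$val_f1[min(epoch, nrow(h))]
}
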