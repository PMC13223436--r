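# Metrics panel: confusion matrix, classification report, AUC, ANOVA,
# class correlations -- checked against direct counting/concordance oracles.

test_that("confusion matrix counts in vocabulary order", {
  cm <- confusion_matrix(c("a", "a", "b", "b"), c("a", "b", "b", "b"),
                         c("a", "b"))
  expect_equal(unname(cm), rbind(c(1L, 1L), c(0L, 2L)))
  # perfect predictions are diagonal
  cmp <- confusion_matrix(c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(unname(cmp), diag(1L, 3))
  # empty input gives an all-zero matrix over the given vocabulary
  cme <- confusion_matrix(character(0), character(0), c("a", "b"))
  expect_equal(sum(cme), 0L)
  expect_error(confusion_matrix("a", "z", c("a", "b")), "unknown label")
})

test_that("classification report: hand-computed binary case", {
  cm <- matrix(c(8L, 1L, 2L, 9L), 2, 2,
               dimnames = list(c("n", "p"), c("n", "p")))
  # cm[1,] = (8, 2); cm[2,] = (1, 9); class "p": TP 9, FP 2, FN 1, TN 8
  r <- classification_report(cm)
  expect_equal(r$per_class$precision[2], 9 / 11)
  expect_equal(r$per_class$recall[2], 0.9)
  expect_equal(r$per_class$specificity[2], 0.8)
  expect_equal(r$per_class$f1[2], 2 * (9 / 11) * 0.9 / (9 / 11 + 0.9))
  expect_equal(r$accuracy, 17 / 20)
  expect_equal(r$error_rate, 3 / 20)
  # diagonal matrix: everything is 1, error 0
  rp <- classification_report(diag(5L, 3))
  expect_true(all(rp$per_class$f1 == 1))
  expect_equal(rp$error_rate, 0)
})

test_that("zero-denominator metrics are 0 and flagged", {
  # class "b" never true and never predicted: all its denominators except
  # specificity vanish
  cm <- matrix(c(4L, 0L, 0L, 0L), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  r <- classification_report(cm)
  expect_equal(r$per_class$precision[2], 0)
  expect_equal(r$per_class$recall[2], 0)
  expect_true(r$per_class$zero_denominator[2])
})

test_that("report matches the exhaustive counting oracle on random cases", {
  classes <- c("w", "x", "y", "z")
  for (case in 1:50) {
    n <- 3L + (case %% 40L)
    true <- with_seed(case, sample(classes, n, replace = TRUE))
    pred <- with_seed(case + 1000L, sample(classes, n, replace = TRUE))
    r <- classification_report(confusion_matrix(true, pred, classes))
    o <- oracle_report(true, pred, classes)
    expect_equal(unname(as.matrix(r$per_class[, 2:5])),
                 unname(o$per_class), tolerance = 1e-12)
    expect_equal(unlist(r$macro[c("precision", "recall", "specificity",
                                  "f1")], use.names = FALSE),
                 unname(o$macro), tolerance = 1e-12)
    expect_equal(r$accuracy, o$accuracy, tolerance = 1e-12)
  }
})

test_that("one-vs-rest AUC: degenerate cases and concordance example", {
  # perfectly separated
  probs <- cbind(c(0.9, 0.8, 0.1, 0.2))
  probs <- cbind(probs, 1 - probs)
  colnames(probs) <- c("p", "n")
  a <- auc_roc_ovr(c("p", "p", "n", "n"), probs)
  expect_equal(unname(a$per_class["p"]), 1.0)
  # all scores equal: ties counted 1/2 give 0.5
  pe <- matrix(0.5, 4, 2, dimnames = list(NULL, c("p", "n")))
  expect_equal(unname(auc_roc_ovr(c("p", "p", "n", "n"), pe)$per_class["p"]),
               0.5)
  # positives {0.9, 0.8} vs negatives {0.3, 0.85}: 3 of 4 concordant pairs
  s <- cbind(c(0.9, 0.8, 0.3, 0.85))
  tab <- cbind(s, 1 - s)
  colnames(tab) <- c("p", "n")
  expect_equal(unname(auc_roc_ovr(c("p", "p", "n", "n"), tab)$per_class["p"]),
               0.75)
})

test_that("rank-statistic AUC equals the pairwise concordance oracle", {
  for (case in 1:50) {
    n <- 5L + (case %% 30L)
    scores <- with_seed(case, round(stats::runif(n), 2))  # forces ties
    is_pos <- with_seed(case + 500L, stats::runif(n) < 0.4)
    if (!any(is_pos) || all(is_pos)) next
    expect_equal(pneumonet:::auc_binary(scores, is_pos),
                 oracle_auc(scores, is_pos), tolerance = 1e-12)
  }
})

test_that("classes without positives are excluded from the macro AUC", {
  probs <- matrix(c(0.6, 0.7, 0.4, 0.3), 2, 2,
                  dimnames = list(NULL, c("a", "b")))
  expect_warning(a <- auc_roc_ovr(c("a", "a"), probs), "excluded")
  expect_true(is.na(a$per_class["b"]))
  expect_equal(a$macro, unname(a$per_class["a"]))
})

test_that("one-way ANOVA: direct arithmetic and degenerate cases", {
  t1 <- anova_one_way(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(t1$ss_between, 13.5)
  expect_equal(t1$ss_within, 4)
  expect_equal(t1$df_between, 1)
  expect_equal(t1$df_within, 4)
  expect_equal(t1$f_value, 13.5)
  expect_equal(t1$ss_total, 17.5)
  expect_equal(t1$p_value, stats::pf(13.5, 1, 4, lower.tail = FALSE))
  # identical groups: no between-group variance
  t2 <- anova_one_way(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(t2$ss_between, 0)
  expect_equal(t2$f_value, 0)
  # zero within-group variance flags an infinite F
  t3 <- anova_one_way(list(c(1, 1), c(2, 2)))
  expect_true(is.infinite(t3$f_value))
  expect_true(t3$zero_within_variance)
  # from-SS form satisfies the table identities
  t4 <- anova_from_ss(10, 2, 20, 10)
  expect_equal(t4$ms_between, 5)
  expect_equal(t4$ms_within, 2)
  expect_equal(t4$f_value, 2.5)
  expect_equal(t4$ss_total, 30)
  expect_equal(t4$df_total, 12)
  # cross-check groups form against base R aov on seeded data
  g <- with_seed(12L, list(stats::rnorm(8), stats::rnorm(8, 0.5),
                           stats::rnorm(8, 1)))
  mine <- anova_one_way(g)
  base_tab <- summary(stats::aov(y ~ grp, data.frame(
    y = unlist(g), grp = factor(rep(1:3, each = 8)))))[[1]]
  expect_equal(mine$f_value, base_tab$`F value`[1], tolerance = 1e-10)
  expect_equal(mine$p_value, base_tab$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("class correlation grid: identities and Pearson formula", {
  f <- rbind(c(1, 2, 3), c(1, 2, 3), c(2, 4, 6), c(2, 4, 6))
  lab <- c("a", "a", "b", "b")
  cc <- class_correlation(f, lab)
  expect_equal(unname(diag(cc)), c(1, 1))
  expect_equal(cc["a", "b"], 1)        # proportional means correlate fully
  # anti-correlated means
  v <- c(-1, 0, 1)
  f2 <- rbind(v, v, -v, -v)
  cc2 <- class_correlation(f2, lab)
  expect_equal(cc2["a", "b"], -1)
  # seeded case against the direct formula
  f3 <- with_seed(13L, matrix(stats::rnorm(6 * 5), 6, 5))
  lab3 <- rep(c("a", "b", "c"), each = 2)
  cc3 <- class_correlation(f3, lab3)
  m_a <- colMeans(f3[1:2, ]); m_b <- colMeans(f3[3:4, ])
  expect_equal(cc3["a", "b"], stats::cor(m_a, m_b), tolerance = 1e-12)
  expect_equal(cc3, t(cc3))
  expect_error(class_correlation(f3, c("a", rep("b", 5))), ">= 2 samples")
})

test_that("uniform random predictions score at chance level", {
  n <- 10000L
  true <- with_seed(14L, sample(4L, n, replace = TRUE))
  pred <- with_seed(15L, sample(4L, n, replace = TRUE))
  r <- classification_report(confusion_matrix(true, pred, as.character(1:4)))
  se <- sqrt(0.25 * 0.75 / n)
  expect_lt(abs(r$accuracy - 0.25), 3 * se)
})
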