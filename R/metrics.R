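# Evaluation panel: confusion matrix, per-class and macro classification
# metrics, one-vs-rest AUC, class-correlation grid, and one-way ANOVA.

#' Confusion matrix over a fixed class vocabulary
#'
#' Rows are true classes, columns predicted classes, in vocabulary order.
#'
#' @param true_labels,predicted_labels equal-length vectors over `vocabulary`.
#' @param vocabulary class labels defining row/column order; defaults to the
#'   sorted union of observed labels.
#' @return Integer `K x K` matrix with dimnames.
#' @export
confusion_matrix <- function(true_labels, predicted_labels,
                             vocabulary = NULL) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (length(true_labels) != length(predicted_labels)) {
    stop("label sequences have different lengths")
  }
  if (is.null(vocabulary)) {
    vocabulary <- sort(unique(c(true_labels, predicted_labels)))
  }
  bad <- setdiff(unique(c(true_labels, predicted_labels)), vocabulary)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  K <- length(vocabulary)
  cm <- matrix(0L, K, K, dimnames = list(true = vocabulary,
                                         predicted = vocabulary))
  if (length(true_labels)) {
    t_i <- match(true_labels, vocabulary)
    p_i <- match(predicted_labels, vocabulary)
    for (i in seq_along(t_i)) cm[t_i[i], p_i[i]] <- cm[t_i[i], p_i[i]] + 1L
  }
  cm
}

#' Per-class and macro classification metrics from a confusion matrix
#'
#' One-vs-rest per class: precision `TP/(TP+FP)`, recall/sensitivity
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)`, and F1 as the harmonic mean of
#' that class's precision and recall.  Macro values are unweighted class
#' means; accuracy is `trace/total` and `error_rate = 1 - accuracy`.
#' Metrics with a zero denominator are reported as 0 and flagged.
#'
#' @param cm confusion matrix (rows true, columns predicted).
#' @return Object of class `"pneumo_report"`: list with `per_class` (data
#'   frame), `macro` (named list), `accuracy`, `error_rate`, `n`.
#' @export
classification_report <- function(cm) {
  total <- sum(cm)
  if (total <= 0) stop("confusion matrix is empty")
  K <- nrow(cm)
  cls <- rownames(cm)
  if (is.null(cls)) cls <- as.character(seq_len(K))
  safe_div <- function(num, den) {
    list(v = if (den == 0) 0 else num / den, flag = den == 0)
  }
  per <- data.frame(class = cls, precision = 0, recall = 0, specificity = 0,
                    f1 = 0, support = 0L, zero_denominator = FALSE,
                    stringsAsFactors = FALSE)
  for (k in seq_len(K)) {
    TP <- cm[k, k]
    FP <- sum(cm[-k, k])
    FN <- sum(cm[k, -k])
    TN <- total - TP - FP - FN
    p <- safe_div(TP, TP + FP)
    r <- safe_div(TP, TP + FN)
    s <- safe_div(TN, TN + FP)
    f <- safe_div(2 * p$v * r$v, p$v + r$v)
    per$precision[k] <- p$v; per$recall[k] <- r$v
    per$specificity[k] <- s$v; per$f1[k] <- f$v
    per$support[k] <- TP + FN
    per$zero_denominator[k] <- p$flag || r$flag || s$flag || f$flag
  }
  acc <- sum(diag(cm)) / total
  structure(list(per_class = per,
                 macro = list(precision = mean(per$precision),
                              recall = mean(per$recall),
                              specificity = mean(per$specificity),
                              f1 = mean(per$f1)),
                 accuracy = acc, error_rate = 1 - acc, n = total,
                 confusion = cm),
            class = "pneumo_report")
}

#' @export
print.pneumo_report <- function(x, digits = 4, ...) {
  cat("Classification report (n = ", x$n, ")\n", sep = "")
  print(cbind(x$per_class[1], round(x$per_class[2:5], digits),
              x$per_class["support"]), row.names = FALSE)
  cat(sprintf("accuracy %.4f  error rate %.4f  macro F1 %.4f\n",
              x$accuracy, x$error_rate, x$macro$f1))
  invisible(x)
}

# Binary AUC by the rank statistic (ties counted 1/2 via average ranks).
auc_binary <- function(scores, is_pos) {
  np <- sum(is_pos); nn <- sum(!is_pos)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[is_pos]) - np * (np + 1) / 2) / (np * nn)
}

#' One-vs-rest AUC-ROC per class and macro
#'
#' Per class, the probability that a random positive outranks a random
#' negative under that class's predicted probability, ties counted 1/2
#' (computed by the Mann-Whitney rank statistic).  Classes with no positives
#' or no negatives get `NA` and are excluded from the macro mean with a
#' warning.
#'
#' @param true_labels vector of true labels.
#' @param probability_table `n x K` matrix of class probabilities with column
#'   names (or columns in vocabulary order).
#' @param vocabulary optional class order; defaults to the table's colnames.
#' @return List with `per_class` (named vector) and `macro`.
#' @export
auc_roc_ovr <- function(true_labels, probability_table, vocabulary = NULL) {
  if (is.null(vocabulary)) vocabulary <- colnames(probability_table)
  if (is.null(vocabulary)) stop("no class vocabulary available")
  rs <- rowSums(probability_table)
  if (any(abs(rs - 1) > 1e-6)) {
    warning("probability rows do not sum to 1 (max deviation ",
            signif(max(abs(rs - 1)), 3), ")")
  }
  true_labels <- as.character(true_labels)
  aucs <- vapply(seq_along(vocabulary), function(k) {
    auc_binary(probability_table[, k], true_labels == vocabulary[k])
  }, numeric(1))
  names(aucs) <- vocabulary
  if (anyNA(aucs)) {
    warning("AUC undefined for class(es) without positives or negatives: ",
            paste(names(aucs)[is.na(aucs)], collapse = ", "),
            "; excluded from the macro mean")
  }
  list(per_class = aucs, macro = mean(aucs, na.rm = TRUE))
}

new_anova_table <- function(ss_b, df_b, ss_w, df_w, zero_within = FALSE) {
  ms_b <- ss_b / df_b
  ms_w <- ss_w / df_w
  f <- if (ms_w == 0) Inf else ms_b / ms_w
  p <- if (is.infinite(f)) 0 else stats::pf(f, df_b, df_w, lower.tail = FALSE)
  structure(list(ss_between = ss_b, df_between = df_b, ms_between = ms_b,
                 ss_within = ss_w, df_within = df_w, ms_within = ms_w,
                 f_value = f, p_value = p,
                 ss_total = ss_b + ss_w, df_total = df_b + df_w,
                 zero_within_variance = zero_within || ms_w == 0),
            class = "pneumo_anova")
}

#' One-way ANOVA from raw groups
#'
#' Textbook between/within decomposition with the F upper-tail p-value.
#' Zero within-group variance yields `F = Inf` with a flag.
#'
#' @param groups list of numeric vectors (>= 2 groups, each >= 2 values).
#' @return Object of class `"pneumo_anova"` (see [anova_from_ss()]).
#' @export
anova_one_way <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(vapply(groups, length, 1L) < 2L)) {
    stop("each group needs >= 2 values")
  }
  all_x <- unlist(groups)
  gm <- mean(all_x)
  means <- vapply(groups, mean, numeric(1))
  ns <- vapply(groups, length, numeric(1))
  ss_b <- sum(ns * (means - gm)^2)
  ss_w <- sum(vapply(seq_along(groups),
                     function(i) sum((groups[[i]] - means[i])^2), numeric(1)))
  new_anova_table(ss_b, df_b = length(groups) - 1, ss_w = ss_w,
                  df_w = sum(ns) - length(groups))
}

#' One-way ANOVA table from sums of squares
#'
#' Builds the full table (mean squares, F, p, totals) from the between/within
#' sums of squares and degrees of freedom, satisfying `MS = SS/df`,
#' `SS_total = SS_b + SS_w`, `df_total = df_b + df_w`, `F = MS_b/MS_w`.
#'
#' @param ss_b,df_b between-groups sum of squares and degrees of freedom.
#' @param ss_w,df_w within-groups sum of squares and degrees of freedom.
#' @return Object of class `"pneumo_anova"`.
#' @export
anova_from_ss <- function(ss_b, df_b, ss_w, df_w) {
  stopifnot(df_b > 0, df_w > 0, ss_b >= 0, ss_w >= 0)
  new_anova_table(ss_b, df_b, ss_w, df_w)
}

#' @export
print.pneumo_anova <- function(x, ...) {
  tab <- data.frame(
    Component = c("Between Groups", "Within Groups", "Total"),
    SS = c(x$ss_between, x$ss_within, x$ss_total),
    df = c(x$df_between, x$df_within, x$df_total),
    MS = c(x$ms_between, x$ms_within, NA),
    F = c(x$f_value, NA, NA),
    p = c(x$p_value, NA, NA))
  print(tab, row.names = FALSE, digits = 5, na.print = "-")
  if (x$zero_within_variance) cat("note: zero within-group variance\n")
  invisible(x)
}

#' Pearson correlation between class-mean feature vectors
#'
#' Averages feature vectors within each class and correlates every pair of
#' class means; symmetric with unit diagonal.  Zero-variance class means give
#' `NA` entries with a warning.
#'
#' @param feature_vectors `n x d` matrix (e.g. pooled features from the
#'   network's global-average-pooling layer).
#' @param labels length-`n` class labels (>= 2 samples per class).
#' @return `K x K` correlation matrix with class dimnames.
#' @export
class_correlation <- function(feature_vectors, labels) {
  labels <- as.factor(labels)
  if (any(table(labels) < 2L)) stop("need >= 2 samples per class")
  means <- rowsum(feature_vectors, group = labels) /
    as.vector(table(labels)[levels(labels)])
  K <- nrow(means)
  out <- matrix(1, K, K, dimnames = list(levels(labels), levels(labels)))
  sds <- apply(means, 1L, stats::sd)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (i == j) next
    if (sds[i] == 0 || sds[j] == 0) {
      out[i, j] <- NA_real_
    } else {
      out[i, j] <- stats::cor(means[i, ], means[j, ])
    }
  }
  if (anyNA(out)) warning("zero-variance class mean: correlation undefined ",
                          "for some pairs (reported as NA)")
  out
}
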