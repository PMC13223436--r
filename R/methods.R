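# S3 methods for fitted models.

#' Predict from a fitted hybrid classifier
#'
#' Applies the model's stored preprocessing (equalization, resize,
#' normalization with the training statistics) and an evaluation-mode forward
#' pass (dropout disabled).
#'
#' @param object a `"pneumonet"`.
#' @param newdata a `"pneumo_dataset"`, list of image matrices, or a single
#'   matrix.
#' @param type `"prob"` for the class-probability matrix, `"class"` for a
#'   factor of predicted labels.
#' @param ... unused.
#' @return Matrix of probabilities (columns named by class) or a factor.
#' @export
predict.pneumonet <- function(object, newdata,
                              type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "pneumo_dataset")) newdata <- newdata$images
  if (is.matrix(newdata)) newdata <- list(newdata)
  pre <- preprocess_images(newdata, object$config$input_size,
                           object$control$equalize)
  norm <- lapply(pre, normalize_zscore, stats = object$stats)
  probs <- net_eval_probs(norm, object$params, object$config)
  colnames(probs) <- object$classes
  if (type == "prob") return(probs)
  factor(object$classes[max.col(probs, ties.method = "first")],
         levels = object$classes)
}

#' @export
print.pneumonet <- function(x, ...) {
  cat("Hybrid fire-module/attention pneumonia classifier\n")
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  cat("  input:", x$config$input_size, "x", x$config$input_size,
      " fire modules:", length(x$config$fire),
      " attention blocks:", x$config$n_attention_blocks, "\n")
  cat("  parameters:", format(sum(vapply(x$params, length, 1L)),
                              big.mark = ","), "\n")
  cat("  epochs trained:", nrow(x$history),
      " final val accuracy:", round(utils::tail(x$history$val_acc, 1), 4),
      "\n")
  cat("  dropout:", if (x$control$dropout_search) "adaptive search"
      else paste("fixed", x$control$fixed_dropout),
      "(final rate", round(x$dropout_rate, 3), ")\n")
  invisible(x)
}

#' @export
summary.pneumonet <- function(object, ...) {
  structure(list(model = object, report = object$val$report,
                 auc = object$val$auc, history = object$history),
            class = "summary.pneumonet")
}

#' @export
print.summary.pneumonet <- function(x, ...) {
  print(x$model)
  cat("\nValidation metrics:\n")
  print(x$report)
  cat("macro one-vs-rest AUC:", round(x$auc$macro, 4), "\n")
  invisible(x)
}

#' @export
coef.pneumonet <- function(object, ...) {
  unlist(object$params)
}

#' Training-history plot
#'
#' Training and validation loss per epoch, with the active dropout rate on a
#' secondary panel.
#'
#' @param x a `"pneumonet"`.
#' @param ... passed to `matplot`.
#' @export
plot.pneumonet <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "cross-entropy", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  graphics::plot(h$epoch, h$dropout_rate, type = "s", col = "darkgreen",
                 xlab = "epoch", ylab = "dropout rate",
                 ylim = x$config$dropout_bounds)
  invisible(x)
}

#' Simulate class labels from predicted probabilities
#'
#' Draws labels from the model's predictive distribution for each image, the
#' classifier analogue of simulating from a fitted response distribution.
#'
#' @param object a `"pneumonet"`.
#' @param nsim number of simulated label sets.
#' @param seed optional integer seed.
#' @param newdata images to simulate for (defaults to the validation set's
#'   stored probabilities).
#' @param ... unused.
#' @return A data frame with `nsim` factor columns.
#' @export
simulate.pneumonet <- function(object, nsim = 1, seed = NULL,
                               newdata = NULL, ...) {
  probs <- if (is.null(newdata)) object$val$probs
           else predict(object, newdata, type = "prob")
  draw <- function() {
    idx <- apply(probs, 1L, function(p) sample.int(length(p), 1L, prob = p))
    factor(object$classes[idx], levels = object$classes)
  }
  sims <- if (is.null(seed)) replicate(nsim, draw(), simplify = FALSE)
          else with_seed(seed, replicate(nsim, draw(), simplify = FALSE))
  out <- as.data.frame(sims, col.names = paste0("sim_", seq_len(nsim)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Residuals of a fitted classifier
#'
#' Response residuals on the validation set: one-hot truth minus predicted
#' probability, per class.
#'
#' @param object a `"pneumonet"`.
#' @param ... unused.
#' @return Matrix with one row per validation image, one column per class.
#' @export
residuals.pneumonet <- function(object, ...) {
  probs <- object$val$probs
  y <- as.integer(object$val$truth)
  Y <- matrix(0, nrow(probs), ncol(probs))
  Y[cbind(seq_len(nrow(probs)), y)] <- 1
  r <- Y - probs
  colnames(r) <- object$classes
  r
}
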