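#' Fit a causal convolutional subtype classifier
#'
#' The central fitting function of the package.  Trains a causally padded
#' 1-D convolutional network on importance-ranked feature sequences: the
#' network reads each patient's features most-important-first, and its
#' output at the end of the sequence is the subtype probability vector,
#' mimicking a neurologist who accumulates evidence feature by feature.
#'
#' @param x Numeric matrix of ranked feature sequences (one row per
#'   patient), typically a [to_sequence()] result.  Column order matters:
#'   position 1 is the most important feature.
#' @param y Integer class labels in `0:(n_classes - 1)`.
#' @param variant Architecture variant, `"V1"`-`"V4"` (see
#'   [network_spec()]); `"V4"` — both pooling and convolution branches plus
#'   the fused first-layer output — is the default.
#' @param loss A [loss_config()]; the default KL-regularized focal loss
#'   targets severe class imbalance.
#' @param epochs,batch_size Training schedule (defaults 100 and 32).
#' @param learning_rate Adam step size.
#' @param seed Integer seed controlling weight initialization and batch
#'   shuffling; fits are reproducible.
#' @param spec Optional full [network_spec()]; overrides `variant` and
#'   infers nothing (its `sequence_length` must match `ncol(x)`).
#' @param class_labels Optional character names of the classes (defaults to
#'   the TOAST subtypes when there are five classes).
#' @return An object of class `causal_cnn` with components `net` (the
#'   trained `causal_net`), `loss`, `history`, `data` (the training
#'   matrix and labels), `class_labels` and `call`.  Supports `print()`,
#'   `summary()`, `predict()`, `coef()`, `plot()`, `residuals()` and
#'   `simulate()`.
#' @examples
#' \donttest{
#' tab <- generate_cohort(cohort_spec(class_counts = c(40, 10, 20, 8, 12),
#'                                    n_features = 16, n_informative = 8,
#'                                    effect_size = 2, missing_rate = 0,
#'                                    seed = 3))
#' xs <- to_sequence(tab, names(tab$x))
#' fit <- causal_cnn(xs, tab$y, variant = "V4", epochs = 20, seed = 3)
#' print(fit)
#' head(predict(fit))
#' }
#' @export
causal_cnn <- function(x, y, variant = "V4", loss = loss_config(),
                       epochs = 100L, batch_size = 32L,
                       learning_rate = 1e-3, seed = 1L, spec = NULL,
                       class_labels = NULL) {
  x <- as.matrix(x); y <- as.integer(y)
  K <- max(y) + 1L
  if (is.null(spec)) {
    spec <- network_spec(variant = variant, sequence_length = ncol(x),
                         n_classes = max(K, 2L), seed = seed)
  } else if (spec$sequence_length != ncol(x)) {
    stop("spec sequence_length (", spec$sequence_length,
         ") does not match ncol(x) (", ncol(x), ")")
  }
  if (is.null(class_labels))
    class_labels <- if (spec$n_classes == 5L) toast_classes
                    else paste0("class", seq_len(spec$n_classes) - 1L)
  net <- build_network(spec)
  net <- train_network(net, x, y, loss = loss, epochs = epochs,
                       batch_size = batch_size,
                       learning_rate = learning_rate, seed = seed)
  structure(list(net = net, loss = loss, history = net$history,
                 data = list(x = unclass(x), y = y),
                 class_labels = class_labels,
                 epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, seed = seed,
                 call = match.call()),
            class = "causal_cnn")
}

#' @export
print.causal_cnn <- function(x, ...) {
  cat("Causal CNN subtype classifier (variant ", x$net$spec$variant, ")\n",
      sep = "")
  cat("  ", nrow(x$data$x), " training samples, sequence length ",
      ncol(x$data$x), ", ", x$net$spec$n_classes, " classes\n", sep = "")
  cat("  ", count_parameters(x), " parameters; loss '", x$loss$name,
      "'; ", length(x$history), " epochs trained\n", sep = "")
  if (length(x$history))
    cat(sprintf("  final training loss: %.4f\n", tail(x$history, 1)))
  invisible(x)
}

#' @export
summary.causal_cnn <- function(object, ...) {
  p <- predict(object)
  rep <- compute_metrics(object$data$y, p,
                         class_labels = object$class_labels)
  out <- list(fit = object, train_metrics = rep)
  class(out) <- "summary.causal_cnn"
  out
}

#' @export
print.summary.causal_cnn <- function(x, ...) {
  print(x$fit)
  cat("\nTraining-set metrics (in-sample, optimistic):\n")
  print(x$train_metrics)
  invisible(x)
}

#' Predicted subtype probabilities or classes
#'
#' @param object A `causal_cnn` fit.
#' @param newdata Matrix of ranked feature sequences; defaults to the
#'   training data.
#' @param type `"prob"` for the probability matrix, `"class"` for argmax
#'   labels (ties toward the lowest class index).
#' @param ... Unused.
#' @return Probability matrix or integer class vector.
#' @export
predict.causal_cnn <- function(object, newdata = NULL,
                               type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- if (is.null(newdata)) object$data$x else as.matrix(newdata)
  p <- predict_proba(object$net, x)
  colnames(p) <- object$class_labels
  if (type == "prob") return(p)
  max.col(p, ties.method = "first") - 1L
}

#' @export
coef.causal_cnn <- function(object, ...) object$net$params

#' @export
plot.causal_cnn <- function(x, ...) {
  if (!length(x$history)) stop("no training history to plot")
  plot(seq_along(x$history), x$history, type = "l",
       xlab = "epoch", ylab = "mean training loss",
       main = paste0("Causal CNN (", x$net$spec$variant, "), loss '",
                     x$loss$name, "'"), ...)
  invisible(x)
}

#' Response residuals of a fitted classifier
#'
#' One-hot indicator of the observed class minus the predicted probability
#' matrix; each row sums to zero for a perfectly calibrated prediction of
#' its own argmax.
#'
#' @param object A `causal_cnn` fit.
#' @param ... Unused.
#' @return Numeric matrix (samples x classes).
#' @export
residuals.causal_cnn <- function(object, ...) {
  p <- predict(object)
  onehot <- matrix(0, nrow(p), ncol(p), dimnames = dimnames(p))
  onehot[cbind(seq_len(nrow(p)), object$data$y + 1L)] <- 1
  onehot - p
}

#' Simulate subtype labels from a fitted classifier
#'
#' Draws class labels from the predicted probability distribution of each
#' training sample.
#'
#' @param object A `causal_cnn` fit.
#' @param nsim Number of simulated label vectors.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return Data frame with `nsim` columns of integer labels.
#' @export
simulate.causal_cnn <- function(object, nsim = 1, seed = NULL, ...) {
  p <- predict(object)
  draw <- function() {
    apply(p, 1L, function(r) sample.int(length(r), 1L, prob = r) - 1L)
  }
  sims <- if (is.null(seed)) replicate(nsim, draw())
          else with_seed(seed, replicate(nsim, draw()))
  as.data.frame(matrix(sims, ncol = nsim,
                       dimnames = list(NULL, paste0("sim_", seq_len(nsim)))))
}
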