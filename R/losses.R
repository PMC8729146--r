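#' Loss configuration
#'
#' Settings of the training loss.  The default, `"kl_focal"`, is the sum of
#' a focal term on the true-class probability and a Kullback-Leibler
#' divergence between the predicted distribution and a label-smoothed
#' target distribution.  The focal exponent `gamma` down-weights easy,
#' confident samples; the KL term keeps the predicted distribution close to
#' the (smoothed) target and acts as a diversity-preserving regularizer
#' during fine-tuning.
#'
#' A one-hot target makes `log(P/Q)` diverge, so the target is
#' label-smoothed (`Q = (1 - s) * onehot + s / K`) and both distributions
#' are clipped at `clip_epsilon` and renormalized before any logarithm is
#' taken.
#'
#' @param name One of `"kl_focal"`, `"focal"`, `"cross_entropy"`, `"kl"`,
#'   `"mse"`, `"mae"`, `"mape"`, `"msle"`.  The error-based losses and plain
#'   cross-entropy/KL are thin pass-throughs for the loss-comparison
#'   harness.
#' @param gamma Non-negative focal exponent; 0 recovers cross-entropy.
#' @param clip_epsilon Probability clipping bound, in (0, 0.5).
#' @param label_smoothing Smoothing mass in \[0, 0.5) moved from the true
#'   class to the others.
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(name = "kl_focal", gamma = 2, clip_epsilon = 1e-7,
                        label_smoothing = 0.05) {
  name <- match.arg(name, c("kl_focal", "focal", "cross_entropy", "kl",
                            "mse", "mae", "mape", "msle"))
  if (gamma < 0) stop("'gamma' must be non-negative")
  if (clip_epsilon <= 0 || clip_epsilon >= 0.5)
    stop("'clip_epsilon' must lie in (0, 0.5)")
  if (label_smoothing < 0 || label_smoothing >= 0.5)
    stop("'label_smoothing' must lie in [0, 0.5)")
  structure(list(name = name, gamma = gamma, clip_epsilon = clip_epsilon,
                 label_smoothing = label_smoothing),
            class = "loss_config")
}

clip_probs <- function(p, eps) pmin(pmax(p, eps), 1)

#' Focal loss
#'
#' `FL(p) = -(1 - p)^gamma * log(p)` on the predicted probability of the
#' true class, averaged over samples.  With `gamma = 0` this is the
#' cross-entropy of the true class; larger `gamma` suppresses the
#' contribution of well-classified samples, which counteracts severe class
#' imbalance.
#'
#' @param p_true Numeric vector of true-class probabilities.
#' @param gamma Non-negative focal exponent.
#' @param clip_epsilon Lower clipping bound applied to `p_true`.
#' @return Mean focal loss (non-negative scalar).
#' @examples
#' focal_loss(0.25, gamma = 2)   # 0.5625 * log(4)
#' @export
focal_loss <- function(p_true, gamma = 2, clip_epsilon = 1e-7) {
  p <- clip_probs(p_true, clip_epsilon)
  mean(-(1 - p)^gamma * log(p))
}

#' Kullback-Leibler divergence of predicted from target distributions
#'
#' `KL(P || Q) = sum_j P_j * log(P_j / Q_j)` per sample.  Both
#' distributions are clipped at `clip_epsilon` and renormalized first, so
#' the value is finite even for one-hot targets; by Gibbs' inequality it is
#' non-negative and zero exactly when `P = Q`.
#'
#' @param p Predicted distribution: numeric vector, or matrix with one
#'   distribution per row.
#' @param q Target distribution(s), same shape as `p`.
#' @param clip_epsilon Clipping bound.
#' @return Numeric vector of per-row divergences.
#' @export
kl_term <- function(p, q, clip_epsilon = 1e-7) {
  if (is.null(dim(p))) p <- matrix(p, 1L)
  if (is.null(dim(q))) q <- matrix(q, 1L)
  if (!all(dim(p) == dim(q))) stop("'p' and 'q' dimensions differ")
  p <- clip_probs(p, clip_epsilon); p <- p / rowSums(p)
  q <- clip_probs(q, clip_epsilon); q <- q / rowSums(q)
  rowSums(p * log(p / q))
}

#' Label-smoothed one-hot target distributions
#'
#' @param y Integer labels in `0:(n_classes - 1)`.
#' @param n_classes Number of classes.
#' @param smoothing Mass `s` redistributed uniformly: the true class gets
#'   `1 - s + s / K`, every other class `s / K`.
#' @return Matrix (samples x classes).
#' @export
smooth_labels <- function(y, n_classes, smoothing = 0.05) {
  y <- as.integer(y)
  q <- matrix(smoothing / n_classes, length(y), n_classes)
  q[cbind(seq_along(y), y + 1L)] <- 1 - smoothing + smoothing / n_classes
  q
}

#' KL-regularized focal loss
#'
#' `KFL = FL(p_x) + KL(P || Q)` per sample, averaged over the batch, where
#' `p_x` is the predicted probability of the true class (the argmax of the
#' target row `Q`) and `Q` is the label-smoothed target distribution.
#'
#' @param p Predicted probability matrix (samples x classes).
#' @param q Target distribution matrix, e.g. from [smooth_labels()].
#' @param config A [loss_config()] supplying `gamma` and `clip_epsilon`.
#' @return Mean loss (scalar).
#' @export
kl_focal_loss <- function(p, q, config = loss_config()) {
  if (is.null(dim(p))) p <- matrix(p, 1L)
  if (is.null(dim(q))) q <- matrix(q, 1L)
  if (!all(dim(p) == dim(q))) stop("'p' and 'q' dimensions differ")
  true_class <- max.col(q, ties.method = "first")
  p_true <- p[cbind(seq_len(nrow(p)), true_class)]
  fl <- -(1 - clip_probs(p_true, config$clip_epsilon))^config$gamma *
    log(clip_probs(p_true, config$clip_epsilon))
  mean(fl + kl_term(p, q, config$clip_epsilon))
}

# ---- training-time loss values and gradients dL/dP --------------------------
# Each returns the mean loss over the batch and the gradient of that mean
# with respect to the probability matrix `p`.  One-hot targets are used for
# the error-based losses; kl/kl_focal use the smoothed target.

loss_value_grad <- function(config, p, y) {
  n <- nrow(p); K <- ncol(p)
  eps <- config$clip_epsilon
  onehot <- matrix(0, n, K)
  onehot[cbind(seq_len(n), y + 1L)] <- 1
  pc <- clip_probs(p, eps)
  idx <- cbind(seq_len(n), y + 1L)
  dp <- matrix(0, n, K)

  switch(config$name,
    kl_focal = {
      q <- clip_probs(smooth_labels(y, K, config$label_smoothing), eps)
      q <- q / rowSums(q)
      g <- config$gamma
      pt <- pc[idx]
      fl <- -(1 - pt)^g * log(pt)
      kl <- rowSums(pc * log(pc / q))
      dp <- (log(pc / q) + 1) / n
      dp[idx] <- dp[idx] +
        (g * (1 - pt)^(g - 1) * log(pt) - (1 - pt)^g / pt) / n
      list(value = mean(fl + kl), dp = dp)
    },
    focal = {
      g <- config$gamma
      pt <- pc[idx]
      dp[idx] <- (g * (1 - pt)^(g - 1) * log(pt) - (1 - pt)^g / pt) / n
      list(value = mean(-(1 - pt)^g * log(pt)), dp = dp)
    },
    cross_entropy = {
      pt <- pc[idx]
      dp[idx] <- -1 / pt / n
      list(value = mean(-log(pt)), dp = dp)
    },
    kl = {
      # KL(Q || P) with one-hot Q reduces to the true-class cross-entropy.
      q <- clip_probs(onehot, eps); q <- q / rowSums(q)
      dp <- -q / pc / n
      list(value = mean(rowSums(q * log(q / pc))), dp = dp)
    },
    mse = {
      dp <- 2 * (p - onehot) / (n * K)
      list(value = mean((p - onehot)^2), dp = dp)
    },
    mae = {
      dp <- sign(p - onehot) / (n * K)
      list(value = mean(abs(p - onehot)), dp = dp)
    },
    mape = {
      d <- pmax(abs(onehot), eps)
      dp <- sign(p - onehot) / d / (n * K)
      list(value = mean(abs(p - onehot) / d), dp = dp)
    },
    msle = {
      r <- log1p(p) - log1p(onehot)
      dp <- 2 * r / (1 + p) / (n * K)
      list(value = mean(r^2), dp = dp)
    })
}
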