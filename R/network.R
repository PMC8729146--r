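#' Network architecture specification
#'
#' Hyperparameters of the causal convolutional classifier.  All four
#' variants share a first causally padded convolution; they differ in what
#' follows it:
#' \describe{
#'   \item{V1}{second causal convolution, then the head}
#'   \item{V2}{max pooling instead of the second convolution}
#'   \item{V3}{max-pool branch and convolution branch concatenated
#'     channel-wise}
#'   \item{V4}{as V3, additionally fusing the (stride-aligned) output of the
#'     first convolution into the concatenation}
#' }
#' The head is global average pooling over time, a dense hidden layer, and
#' a softmax class-probability output.
#'
#' @param variant One of `"V1"`, `"V2"`, `"V3"`, `"V4"`.
#' @param sequence_length Length of the ranked feature sequence (t + 1).
#' @param conv1,conv2 Numeric vectors `(filters, kernel, stride)` of the two
#'   causal convolutions.
#' @param pool Numeric vector `(window, stride)` of the max-pooling branch.
#' @param head_width Units of the dense hidden layer.
#' @param n_classes Number of output classes.
#' @param seed Seed for weight initialization.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(variant = "V4",
                         sequence_length = 93L,
                         conv1 = c(filters = 32L, kernel = 4L, stride = 1L),
                         conv2 = c(filters = 24L, kernel = 3L, stride = 2L),
                         pool = c(window = 2L, stride = 2L),
                         head_width = 64L,
                         n_classes = 5L,
                         seed = 1L) {
  variant <- match.arg(variant, c("V1", "V2", "V3", "V4"))
  conv1 <- as.integer(conv1); conv2 <- as.integer(conv2)
  pool <- as.integer(pool)
  if (any(c(conv1, conv2, pool, head_width, sequence_length) < 1L))
    stop("all widths, kernels and strides must be positive")
  if (n_classes < 2L) stop("'n_classes' must be at least 2")
  if (sequence_length < max(conv1[2L], conv2[2L], pool[1L]))
    stop("sequence shorter than a kernel/pool window")
  structure(list(variant = variant,
                 sequence_length = as.integer(sequence_length),
                 conv1 = setNames(conv1, c("filters", "kernel", "stride")),
                 conv2 = setNames(conv2, c("filters", "kernel", "stride")),
                 pool = setNames(pool, c("window", "stride")),
                 head_width = as.integer(head_width),
                 n_classes = as.integer(n_classes),
                 seed = as.integer(seed)),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat("Causal CNN spec, variant", x$variant, "\n")
  cat("  sequence length:", x$sequence_length,
      " classes:", x$n_classes, "\n")
  cat("  conv1:", paste(x$conv1, collapse = "/"),
      " conv2:", paste(x$conv2, collapse = "/"),
      " pool:", paste(x$pool, collapse = "/"),
      " head:", x$head_width, "\n")
  invisible(x)
}

# ---- primitive layers -------------------------------------------------------
# Activations are 3-D arrays (batch, time, channels).

#' Causally padded 1-D convolution
#'
#' Applies a 1-D convolution with left-only (causal) padding of `kernel - 1`
#' zeros, so the output at sequence position t depends only on input
#' positions at or before t — the network can never read a feature ranked
#' below the one currently under consideration.
#'
#' @param x Array `(batch, time, channels_in)`, or a matrix
#'   `(batch, time)` treated as a single channel.
#' @param weights Matrix `(kernel * channels_in, filters)`; rows ordered
#'   kernel-offset-major (all input channels of offset 1, then offset 2,
#'   ...), with offset `kernel` the current position.
#' @param bias Numeric vector of length `filters`.
#' @param stride Temporal stride; output length is `ceiling(time / stride)`.
#' @return Array `(batch, ceiling(time / stride), filters)`.
#' @export
causal_conv1d <- function(x, weights, bias, stride = 1L) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  conv_forward(x, weights, bias,
               k = nrow(weights) / dim(x)[3L], stride = stride)$out
}

conv_forward <- function(a, w, b, k, stride) {
  d <- dim(a); n <- d[1L]; L <- d[2L]; cin <- d[3L]
  k <- as.integer(k); stride <- as.integer(stride)
  lout <- (L - 1L) %/% stride + 1L
  ap <- array(0, c(n, L + k - 1L, cin))
  ap[, k:(L + k - 1L), ] <- a
  # cols[j, r]: padded time index of kernel offset r for output position j
  cols <- outer(seq(0L, by = stride, length.out = lout), seq_len(k), `+`)
  z <- matrix(rep(b, each = n * lout), n * lout, ncol(w))
  for (r in seq_len(k)) {
    sl <- ap[, cols[, r], , drop = FALSE]          # (n, lout, cin)
    dim(sl) <- c(n * lout, cin)
    z <- z + sl %*% w[(r - 1L) * cin + seq_len(cin), , drop = FALSE]
  }
  out <- array(z, c(n, lout, ncol(w)))
  list(out = out, ap = ap, cols = cols,
       dims = list(n = n, L = L, cin = cin, k = k, lout = lout))
}

conv_backward <- function(dout, w, cache) {
  d <- cache$dims
  dz <- matrix(dout, d$n * d$lout, dim(dout)[3L])
  db <- colSums(dz)
  dw <- matrix(0, nrow(w), ncol(w))
  dap <- array(0, c(d$n, d$L + d$k - 1L, d$cin))
  for (r in seq_len(d$k)) {
    rows <- (r - 1L) * d$cin + seq_len(d$cin)
    sl <- cache$ap[, cache$cols[, r], , drop = FALSE]
    dim(sl) <- c(d$n * d$lout, d$cin)
    dw[rows, ] <- crossprod(sl, dz)
    dsl <- dz %*% t(w[rows, , drop = FALSE])
    dim(dsl) <- c(d$n, d$lout, d$cin)
    dap[, cache$cols[, r], ] <- dap[, cache$cols[, r], , drop = FALSE] + dsl
  }
  da <- dap[, d$k:(d$L + d$k - 1L), , drop = FALSE]
  list(da = da, dw = dw, db = db)
}

pool_forward <- function(a, window, stride) {
  d <- dim(a); n <- d[1L]; L <- d[2L]; ch <- d[3L]
  lout <- (L - window) %/% stride + 1L
  if (lout < 1L) stop("sequence shorter than the pooling window")
  st <- seq(1L, by = stride, length.out = lout)
  cur <- a[, st, , drop = FALSE]
  arg <- array(1L, dim(cur))
  for (r in seq_len(window - 1L)) {
    cand <- a[, st + r, , drop = FALSE]
    upd <- cand > cur
    cur[upd] <- cand[upd]
    arg[upd] <- r + 1L
  }
  list(out = cur, arg = arg, st = st, L = L)
}

pool_backward <- function(dout, cache, ch) {
  d <- dim(dout)
  da <- array(0, c(d[1L], cache$L, ch))
  for (r in seq_len(max(cache$arg))) {
    mask <- cache$arg == r
    if (!any(mask)) next
    g <- dout * mask
    da[, cache$st + (r - 1L), ] <- da[, cache$st + (r - 1L), ] + g
  }
  da
}

relu <- function(x) { x[x < 0] <- 0; x }

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# ---- network construction ---------------------------------------------------

glorot <- function(fan_in, fan_out, nr, nc) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

# Channel count entering the head, per variant.
head_channels <- function(spec) {
  f1 <- spec$conv1[["filters"]]; f2 <- spec$conv2[["filters"]]
  switch(spec$variant, V1 = f2, V2 = f1, V3 = f1 + f2, V4 = 2L * f1 + f2)
}

#' Build a causal convolutional classifier
#'
#' Initializes the trainable weights of the network described by a
#' [network_spec()] (Glorot-uniform, seeded).  The returned handle is
#' trained with [train_network()] and queried with [predict_proba()].
#'
#' @param spec A [network_spec()].
#' @return An object of class `causal_net`.
#' @export
build_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  f1 <- spec$conv1[["filters"]]; k1 <- spec$conv1[["kernel"]]
  f2 <- spec$conv2[["filters"]]; k2 <- spec$conv2[["kernel"]]
  hc <- head_channels(spec); hw <- spec$head_width; K <- spec$n_classes
  params <- with_seed(spec$seed, {
    p <- list(w1 = glorot(k1, f1, k1, f1), b1 = numeric(f1))
    if (spec$variant != "V2") {
      p$w2 <- glorot(k2 * f1, f2, k2 * f1, f2)
      p$b2 <- numeric(f2)
    }
    p$wh <- glorot(hc, hw, hc, hw)
    p$bh <- numeric(hw)
    p$wo <- glorot(hw, K, hw, K)
    p$bo <- numeric(K)
    p
  })
  structure(list(spec = spec, params = params, trained = FALSE,
                 history = numeric(0)),
            class = "causal_net")
}

#' @export
print.causal_net <- function(x, ...) {
  cat("Causal CNN (", x$spec$variant, "), ",
      count_parameters(x), " parameters, ",
      if (x$trained) "trained" else "untrained", "\n", sep = "")
  invisible(x)
}

#' Count trainable parameters
#'
#' Total number of trainable scalars (weights and biases) of a built
#' network.  Deterministic: two builds of the same spec have identical
#' counts.
#'
#' @param model A `causal_net` or a `causal_cnn` fit.
#' @return Integer count.
#' @export
count_parameters <- function(model) {
  if (inherits(model, "causal_cnn")) model <- model$net
  stopifnot(inherits(model, "causal_net"))
  sum(vapply(model$params, length, integer(1)))
}

# Forward pass; with cache = TRUE returns everything backward needs.
net_forward <- function(net, x, cache = FALSE) {
  sp <- net$spec; pm <- net$params
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != sp$sequence_length)
    stop("input has ", ncol(x), " features; spec expects ",
         sp$sequence_length)
  n <- nrow(x)
  a0 <- array(as.numeric(x), c(n, sp$sequence_length, 1L))

  c1 <- conv_forward(a0, pm$w1, pm$b1, k = sp$conv1[["kernel"]],
                     stride = sp$conv1[["stride"]])
  h1 <- relu(c1$out)                              # (n, L1, f1)
  L1 <- dim(h1)[2L]

  branches <- list(); bc <- list()
  if (sp$variant != "V2") {
    c2 <- conv_forward(h1, pm$w2, pm$b2, k = sp$conv2[["kernel"]],
                       stride = sp$conv2[["stride"]])
    h2 <- relu(c2$out)
    branches$conv <- h2
  }
  if (sp$variant != "V1") {
    pl <- pool_forward(h1, sp$pool[["window"]], sp$pool[["stride"]])
    branches$pool <- pl$out
  }
  if (sp$variant == "V4") {
    s <- sp$conv2[["stride"]]
    ds_idx <- seq(s, L1, by = s)
    branches$skip <- h1[, ds_idx, , drop = FALSE]
  }
  lmin <- min(vapply(branches, function(b) dim(b)[2L], integer(1)))
  branches <- lapply(branches, function(b) b[, seq_len(lmin), , drop = FALSE])
  feat <- if (length(branches) == 1L) branches[[1L]] else {
    ch <- vapply(branches, function(b) dim(b)[3L], integer(1))
    out <- array(0, c(n, lmin, sum(ch)))
    at <- 0L
    for (b in branches) {
      out[, , at + seq_len(dim(b)[3L])] <- b
      at <- at + dim(b)[3L]
    }
    out
  }
  fm <- feat
  dim(fm) <- c(n * lmin, dim(feat)[3L])           # global average pool:
  g <- rowsum(fm, rep(seq_len(n), times = lmin)) / lmin
  dimnames(g) <- NULL
  zh <- sweep(g %*% pm$wh, 2L, pm$bh, `+`)
  hh <- relu(zh)
  zo <- sweep(hh %*% pm$wo, 2L, pm$bo, `+`)
  p <- softmax_rows(zo)

  if (!cache) return(list(p = p))
  list(p = p, a0 = a0, c1 = c1, h1 = h1, L1 = L1,
       c2 = if (sp$variant != "V2") c2,
       pl = if (sp$variant != "V1") pl,
       ds_idx = if (sp$variant == "V4") ds_idx,
       lmin = lmin, feat = feat, g = g, zh = zh, hh = hh)
}

# Backward pass from dL/dz_out (pre-softmax logits gradient).
net_backward <- function(net, cache, dzo) {
  sp <- net$spec; pm <- net$params
  gr <- list()
  gr$wo <- crossprod(cache$hh, dzo)
  gr$bo <- colSums(dzo)
  dhh <- dzo %*% t(pm$wo)
  dzh <- dhh * (cache$zh > 0)
  gr$wh <- crossprod(cache$g, dzh)
  gr$bh <- colSums(dzh)
  dg <- dzh %*% t(pm$wh)                          # (n, head channels)

  d <- dim(cache$feat); n <- d[1L]; lmin <- d[2L]
  dfeat <- array(dg[, rep(seq_len(d[3L]), each = lmin), drop = FALSE] / lmin,
                 d)                               # GAP backward

  f1 <- sp$conv1[["filters"]]; f2 <- sp$conv2[["filters"]]
  dh1 <- array(0, dim(cache$h1))
  at <- 0L
  take <- function(nch) {
    sl <- dfeat[, , at + seq_len(nch), drop = FALSE]
    at <<- at + nch
    sl
  }
  pad_time <- function(dcrop, Lfull) {
    full <- array(0, c(n, Lfull, dim(dcrop)[3L]))
    full[, seq_len(lmin), ] <- dcrop
    full
  }
  if (sp$variant != "V2") {                       # conv branch first in concat
    dh2 <- pad_time(take(f2), dim(cache$c2$out)[2L])
    dc2 <- dh2 * (cache$c2$out > 0)
    bk2 <- conv_backward(dc2, pm$w2, cache$c2)
    gr$w2 <- bk2$dw; gr$b2 <- bk2$db
    dh1 <- dh1 + bk2$da
  }
  if (sp$variant != "V1") {
    dpool <- pad_time(take(f1), dim(cache$pl$out)[2L])
    dh1 <- dh1 + pool_backward(dpool, cache$pl, f1)
  }
  if (sp$variant == "V4") {
    dskip <- take(f1)
    dh1[, cache$ds_idx[seq_len(lmin)], ] <-
      dh1[, cache$ds_idx[seq_len(lmin)], ] + dskip
  }
  dc1 <- dh1 * (cache$c1$out > 0)
  bk1 <- conv_backward(dc1, pm$w1, cache$c1)
  gr$w1 <- bk1$dw; gr$b1 <- bk1$db
  gr[names(net$params)]
}

#' Train a causal network
#'
#' Minibatch gradient descent with the Adam optimizer.  Labels must be
#' integers in `0:(n_classes - 1)`.  With `epochs = 0` the model is
#' returned unchanged.
#'
#' @param model A `causal_net` from [build_network()] (or an already trained
#'   one, in which case training continues from the current weights).
#' @param x Numeric matrix (samples x ranked features), e.g. a
#'   [to_sequence()] result.
#' @param y Integer class labels.
#' @param loss A [loss_config()].
#' @param epochs,batch_size Training schedule.
#' @param learning_rate Adam step size.
#' @param seed Seed for batch shuffling; fixed seed gives reproducible
#'   weights.
#' @return The trained `causal_net`, with a per-epoch mean-loss `history`.
#' @export
train_network <- function(model, x, y, loss = loss_config(),
                          epochs = 100L, batch_size = 32L,
                          learning_rate = 1e-3, seed = 1L) {
  stopifnot(inherits(model, "causal_net"))
  x <- unclass(as.matrix(x)); y <- as.integer(y)
  n <- nrow(x)
  if (n == 0L) stop("empty training data")
  if (length(y) != n) stop("length of 'y' must match rows of 'x'")
  K <- model$spec$n_classes
  if (any(y < 0L | y >= K))
    stop("labels must lie in 0..", K - 1L)
  if (epochs == 0L) return(model)

  pm <- model$params
  mom <- lapply(pm, function(p) array(0, dim(p) %||% length(p)))
  vel <- mom
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  history <- numeric(epochs)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      idx <- sample.int(n)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1L, n, by = batch_size)) {
        bi <- idx[start:min(start + batch_size - 1L, n)]
        model$params <- pm
        fw <- net_forward(model, x[bi, , drop = FALSE], cache = TRUE)
        lg <- loss_value_grad(loss, fw$p, y[bi])
        dzo <- softmax_grad(fw$p, lg$dp)
        gr <- net_backward(model, fw, dzo)
        step <- step + 1L
        corr <- learning_rate * sqrt(1 - b2^step) / (1 - b1^step)
        for (nm in names(pm)) {
          mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * gr[[nm]]
          vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * gr[[nm]]^2
          pm[[nm]] <- pm[[nm]] - corr * mom[[nm]] / (sqrt(vel[[nm]]) + eps)
        }
        ep_loss <- ep_loss + lg$value; nb <- nb + 1L
      }
      history[ep] <- ep_loss / nb
    }
  })
  model$params <- pm
  model$trained <- TRUE
  model$history <- c(model$history, history)
  model
}

# Chain dL/dP through the softmax Jacobian to pre-softmax logits.
softmax_grad <- function(p, dp) {
  p * (dp - rowSums(dp * p))
}

#' Class probabilities from a causal network
#'
#' @param model A `causal_net`.
#' @param x Matrix of ranked feature sequences (columns must match the
#'   spec's `sequence_length`).
#' @return A probability matrix, rows summing to 1.
#' @export
predict_proba <- function(model, x) {
  stopifnot(inherits(model, "causal_net"))
  net_forward(model, as.matrix(x))$p
}

#' Intermediate feature maps of the network
#'
#' Returns the post-activation outputs of the causal convolution layers (and
#' the pooling branch where present), mainly to let users verify the
#' causality property: perturbing the input at sequence position t + 1
#' leaves every convolution output at positions up to t unchanged.
#'
#' @param model A `causal_net`.
#' @param x Input matrix.
#' @return List with elements `conv1` and (variant-dependent) `conv2`,
#'   `pool`, each an array `(batch, time, channels)`.
#' @export
feature_maps <- function(model, x) {
  cache <- net_forward(model, as.matrix(x), cache = TRUE)
  out <- list(conv1 = cache$h1)
  if (!is.null(cache$c2)) out$conv2 <- relu(cache$c2$out)
  if (!is.null(cache$pl)) out$pool <- cache$pl$out
  out
}
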