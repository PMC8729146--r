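test_that("causal convolutions never look ahead of the current position", {
  withr::local_seed(31)
  L <- 12L
  for (variant in c("V1", "V2", "V3", "V4")) {
    net <- build_network(tiny_net_spec(variant, sequence_length = L))
    x <- matrix(rnorm(3L * L), 3L, L)
    for (t in c(2L, 5L, 9L)) {
      x2 <- x
      x2[, (t + 1L):L] <- x2[, (t + 1L):L] + rnorm(3L * (L - t))
      a <- feature_maps(net, x)
      b <- feature_maps(net, x2)
      expect_equal(a$conv1[, 1:t, ], b$conv1[, 1:t, ])
      if (!is.null(a$conv2)) {
        s <- net$spec$conv2[["stride"]]
        jt <- sum((seq_len(dim(a$conv2)[2L]) - 1L) * s + 1L <= t)
        if (jt > 0)
          expect_equal(a$conv2[, 1:jt, ], b$conv2[, 1:jt, ])
      }
    }
  }
})

test_that("the causal_conv1d primitive matches a direct sliding-window oracle", {
  withr::local_seed(8)
  n <- 4L; L <- 10L; k <- 3L; f <- 2L
  x <- matrix(rnorm(n * L), n, L)
  w <- matrix(rnorm(k * f), k, f)
  b <- rnorm(f)
  out <- causal_conv1d(x, w, b, stride = 1L)
  xp <- cbind(matrix(0, n, k - 1L), x)            # left padding
  for (t in seq_len(L)) for (j in seq_len(f)) {
    expect_equal(out[, t, j],
                 as.numeric(xp[, t:(t + k - 1L)] %*% w[, j]) + b[j])
  }
})

test_that("parameter counts follow closed forms and the variant ordering", {
  # single causal conv layer with 1 input channel: (k + 1) * f parameters
  sp <- tiny_net_spec("V1")
  net <- build_network(sp)
  k <- sp$conv1[["kernel"]]; f <- sp$conv1[["filters"]]
  expect_equal(length(net$params$w1) + length(net$params$b1), (k + 1) * f)

  counts <- vapply(c("V1", "V2", "V3", "V4"), function(v)
    count_parameters(build_network(network_spec(variant = v))), numeric(1))
  expect_lt(counts[["V2"]], counts[["V1"]])
  expect_lt(counts[["V1"]], counts[["V3"]])
  expect_lt(counts[["V3"]], counts[["V4"]])

  # fusing the first-layer output into the concatenation adds exactly
  # conv1-filters x head-width weights
  def <- network_spec()
  expect_equal(counts[["V4"]] - counts[["V3"]],
               def$conv1[["filters"]] * def$head_width)

  expect_identical(count_parameters(build_network(network_spec())),
                   count_parameters(build_network(network_spec())))
})

test_that("predicted probability rows are normalized and deterministic", {
  withr::local_seed(5)
  net <- build_network(tiny_net_spec("V3"))
  x <- matrix(rnorm(6L * 12L), 6L, 12L)
  p <- predict_proba(net, x)
  expect_equal(rowSums(p), rep(1, 6L), tolerance = 1e-9)
  # duplicated input rows give identical probability rows
  p2 <- predict_proba(net, x[c(1L, 1L), , drop = FALSE])
  expect_equal(p2[1L, ], p2[2L, ])
  expect_error(predict_proba(net, x[, 1:5]), "features")
})

test_that("analytic gradients match finite differences for every variant", {
  withr::local_seed(13)
  x <- matrix(rnorm(5L * 12L), 5L, 12L)
  y <- c(0L, 1L, 2L, 3L, 4L)
  cfg <- loss_config("kl_focal", gamma = 2, label_smoothing = 0.05)
  for (variant in c("V1", "V2", "V3", "V4")) {
    net <- build_network(tiny_net_spec(variant, seed = 13))
    fw <- toastnet:::net_forward(net, x, cache = TRUE)
    lg <- toastnet:::loss_value_grad(cfg, fw$p, y)
    gr <- toastnet:::net_backward(net, fw,
                                  toastnet:::softmax_grad(fw$p, lg$dp))
    loss_at <- function(par) {
      net$params <- par
      toastnet:::loss_value_grad(cfg,
                                 toastnet:::net_forward(net, x)$p, y)$value
    }
    h <- 1e-5
    for (nm in names(net$params)) {
      idx <- withr::with_seed(7, sample(length(net$params[[nm]]),
                                        min(4L, length(net$params[[nm]]))))
      for (i in idx) {
        up <- net$params; up[[nm]][i] <- up[[nm]][i] + h
        dn <- net$params; dn[[nm]][i] <- dn[[nm]][i] - h
        num <- (loss_at(up) - loss_at(dn)) / (2 * h)
        expect_lt(abs(gr[[nm]][i] - num), 1e-6 + 1e-3 * abs(num),
                  label = paste(variant, nm, i, "gradient mismatch"))
      }
    }
  }
})

test_that("training fits a separable toy problem and respects its contract", {
  toy <- separable_toy()
  tr <- 1:90; te <- 91:120
  sp <- network_spec(variant = "V4", sequence_length = 8L,
                     conv1 = c(8L, 3L, 1L), conv2 = c(6L, 2L, 2L),
                     pool = c(2L, 2L), head_width = 16L, n_classes = 2L,
                     seed = 1L)
  net <- build_network(sp)

  expect_identical(train_network(net, toy$x[tr, ], toy$y[tr], epochs = 0L),
                   net)
  expect_error(train_network(net, toy$x[tr, ], rep(5L, 90L)), "labels")

  fit <- train_network(net, toy$x[tr, ], toy$y[tr],
                       loss = loss_config("kl_focal"), epochs = 40L,
                       seed = 1L)
  pred <- max.col(predict_proba(fit, toy$x[te, ])) - 1L
  expect_gte(mean(pred == toy$y[te]), 0.95)
  # loss trends down on a separable problem
  expect_lt(mean(tail(fit$history, 5L)), mean(head(fit$history, 5L)))

  # reproducibility: same seed, same weights
  fit2 <- train_network(build_network(sp), toy$x[tr, ], toy$y[tr],
                        loss = loss_config("kl_focal"), epochs = 40L,
                        seed = 1L)
  expect_equal(fit$params, fit2$params, tolerance = 1e-12)
})

test_that("spec validation rejects degenerate architectures", {
  expect_error(network_spec(sequence_length = 1L), "kernel")
  expect_error(network_spec(n_classes = 1L), "n_classes")
  expect_error(network_spec(conv1 = c(0L, 4L, 1L)), "positive")
})
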