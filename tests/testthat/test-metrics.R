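test_that("perfect predictions score 1 on every metric", {
  y <- c(0L, 1L, 2L, 3L, 4L, 0L, 2L)
  p <- smooth_labels(y, 5L, 0)
  rep <- compute_metrics(y, p)
  expect_equal(rep$overall$accuracy, 1)
  expect_equal(rep$overall$precision, 1)
  expect_equal(rep$overall$recall, 1)
  expect_equal(rep$overall$f1, 1)
  expect_equal(rep$overall$auc, 1)
  expect_equal(sum(rep$confusion), length(y))
  expect_equal(diag(rep$confusion), setNames(tabulate(y + 1L, 5L),
                                             toast_classes))
})

test_that("binary confusion counts reproduce textbook precision/recall/F1", {
  # class 1 as positive: TP = 3, FP = 1, FN = 1, TN = 5
  y <- c(rep(1L, 4L), rep(0L, 6L))
  pred <- c(1L, 1L, 1L, 0L, 1L, 0L, 0L, 0L, 0L, 0L)
  p <- cbind(1 - pred, pred) * 0.8 + 0.1          # rows sum to 1
  rep <- compute_metrics(y, p, class_labels = c("neg", "pos"))
  expect_equal(rep$confusion["pos", "pos"], 3L)
  expect_equal(rep$per_class$precision[2L], 0.75)
  expect_equal(rep$per_class$recall[2L], 0.75)
  expect_equal(rep$per_class$f1[2L], 0.75)
})

test_that("weighted recall equals accuracy on arbitrary predictions", {
  withr::local_seed(30)
  for (i in 1:25) {
    n <- sample(20:60, 1L)
    k <- sample(3:6, 1L)
    y <- c(seq_len(k) - 1L, sample(0:(k - 1L), n - k, replace = TRUE))
    p <- random_proba(n, k)
    rep <- compute_metrics(y, p)
    expect_equal(rep$overall$recall, rep$overall$accuracy,
                 tolerance = 1e-12)
  }
})

test_that("input validation catches malformed probability matrices", {
  y <- c(0L, 1L)
  expect_error(compute_metrics(y, matrix(c(0.5, 0.4, 0.2, 0.6), 2)),
               "sum to 1")
  expect_error(compute_metrics(0L, matrix(1, 1, 1)), "2 classes")
  expect_warning(compute_metrics(c(0L, 0L, 1L), random_proba(3, 4)),
                 "absent")
})

test_that("one-vs-rest AUC agrees with the rank-sum oracle", {
  withr::local_seed(33)
  y <- sample(0:2, 40, replace = TRUE)
  p <- random_proba(40, 3)
  rep <- compute_metrics(y, p)
  rank_auc <- function(pos, score) {
    r <- rank(score)
    (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) /
      (sum(pos) * sum(!pos))
  }
  for (c in 0:2) {
    expect_equal(rep$per_class$auc[c + 1L], rank_auc(y == c, p[, c + 1L]),
                 tolerance = 1e-10)
  }
})

test_that("paired deltas are signed after-minus-before differences", {
  before <- metrics_report(data.frame(
    class = toast_classes,
    precision = c(0.5960, 0.6220, 0.3966, 0.2917, 0.3067),
    recall = c(0.8774, 0.3857, 0.2821, 0.0682, 0.0280),
    f1 = c(0.7042, 0.4705, 0.2910, 0.1020, 0.0507)))
  after <- metrics_report(data.frame(
    class = toast_classes,
    precision = c(0.6559, 0.7208, 0.5690, 0.4785, 0.3943),
    recall = c(0.7552, 0.5343, 0.5392, 0.2747, 0.2391),
    f1 = c(0.6994, 0.5923, 0.5446, 0.3277, 0.2825)))
  d <- report_delta(before, after)
  expect_equal(d$per_class$precision[d$per_class$class == "SAO"], 0.1724)
  expect_equal(d$per_class$recall[d$per_class$class == "LAA"], -0.1222)
  expect_equal(report_delta(before, before)$per_class$precision,
               rep(0, 5))
  other <- metrics_report(data.frame(class = c("A", "B"),
                                     precision = c(0.1, 0.2)))
  expect_error(report_delta(before, other), "class sets")
})

test_that("fold assignment partitions evenly and stratification is enforced", {
  y <- rep(0:1, c(30L, 12L))
  f <- toastnet:::make_folds(y, 5L, stratified = TRUE, seed = 1)
  sizes <- tabulate(f, 5L)
  expect_equal(sum(sizes), 42L)
  expect_lte(diff(range(sizes)), 1L)
  per_class <- table(factor(f, 1:5), y)
  expect_true(all(abs(per_class[, 1] - 6) <= 1))

  f2 <- toastnet:::make_folds(y, 6L, stratified = FALSE, seed = 1)
  expect_lte(diff(range(tabulate(f2, 6L))), 1L)

  expect_error(toastnet:::make_folds(rep(0:1, c(30L, 3L)), 5L, TRUE, 1),
               "stratified = FALSE")
})

test_that("cross-validation runs leave-one-out with fold-internal preprocessing", {
  tab <- generate_cohort(cohort_spec(class_counts = c(8L, 8L),
                                     n_features = 6L, n_informative = 4L,
                                     effect_size = 3, missing_rate = 0.05,
                                     seed = 40))
  factory <- function(x, y, seed) {
    causal_cnn(x, y, epochs = 2L, seed = seed,
               spec = network_spec(variant = "V2", sequence_length = ncol(x),
                                   conv1 = c(4L, 2L, 1L), pool = c(2L, 2L),
                                   head_width = 4L, n_classes = 2L,
                                   seed = seed))
  }
  cv <- suppressWarnings(    # singleton test folds miss one class each
    cross_validate(factory, tab, k = 16L, stratified = FALSE,
                   seed = 2, threshold = -1))
  expect_length(cv$folds, 16L)
  expect_true(all(tabulate(cv$assignments, 16L) == 1L))  # singleton folds
  # confusion totals conserve the cohort across folds
  expect_equal(sum(vapply(cv$folds, function(r) sum(r$confusion),
                          numeric(1))), 16)
  expect_s3_class(cv$mean, "metrics_report")
  expect_error(cross_validate(factory, tab, k = 1L), "at least 2")
})

test_that("experiment grids validate names first and fill every cell", {
  tab <- generate_cohort(cohort_spec(class_counts = c(60L, 25L, 40L, 20L,
                                                      30L),
                                     n_features = 12L, n_informative = 6L,
                                     effect_size = 2, missing_rate = 0,
                                     seed = 50))
  expect_error(run_experiment(list(cohort = tab, variants = "V9")),
               "unknown variant")
  expect_error(run_experiment(list(cohort = tab, losses = "hinge")),
               "unknown loss")
  expect_error(run_experiment(list(cohort = tab, variants = character(0))),
               "empty")
  expect_error(run_experiment(list(cohort = tab,
                                   strategies = list(list(strategy =
                                                            "committee")))),
               "unknown strategy")

  out_dir <- withr::local_tempdir()
  res <- run_experiment(list(cohort = tab, variants = c("V1", "V2", "V3",
                                                        "V4"),
                             losses = "kl_focal", epochs = 2L, seed = 50,
                             threshold = -1, out_dir = out_dir))
  expect_equal(nrow(res$grid), 4L)
  expect_length(res$reports, 4L)
  expect_true(file.exists(file.path(out_dir, "grid.csv")))
  expect_length(list.files(out_dir, pattern = "^metrics_.*json$"), 4L)

  # an alpha sweep of the mixed criterion is one strategy axis
  sweep <- run_experiment(list(
    cohort = tab, epochs = 1L, seed = 50, threshold = -1,
    strategies = list(list(strategy = "mixed", alpha = 0.1),
                      list(strategy = "mixed", alpha = 0.5))))
  expect_equal(nrow(sweep$grid), 2L)
})
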