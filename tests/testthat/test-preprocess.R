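test_that("informative features out-rank noise features in importance", {
  tab <- generate_cohort(tiny_spec(seed = 2, n_features = 30L,
                                   n_informative = 8L, effect_size = 2,
                                   class_counts = c(80L, 30L, 50L, 25L,
                                                    40L)))
  rep <- compute_importance(tab, seed = 2)
  expect_equal(sort(rep$feature), sort(names(tab$x)))
  expect_true(all(rep$importance >= 0))
  expect_equal(sum(rep$importance), 1, tolerance = 1e-8)
  inf <- tab$meta$informative
  expect_gt(mean(rep$importance[inf]), mean(rep$importance[!inf]))
})

test_that("importance is deterministic and zero for constant features", {
  tab <- generate_cohort(tiny_spec(seed = 5))
  tab$x[[3L]] <- 1                                 # constant column
  a <- compute_importance(tab, seed = 7)
  b <- compute_importance(tab, seed = 7)
  expect_identical(a$importance, b$importance)
  expect_equal(a$importance[a$feature == names(tab$x)[3L]], 0)
  single <- tab
  single$y <- rep(0L, length(tab$y))
  expect_error(compute_importance(single), "single-class")
})

test_that("filter_and_rank drops at the threshold inclusively, ranks stably", {
  rep <- structure(data.frame(feature = c("f1", "f2", "f3"),
                              importance = c(0.2, 0.005, 0.0)),
                   class = c("importance_report", "data.frame"))
  out <- filter_and_rank(rep, 0.005)
  expect_equal(out$kept, "f1")
  expect_equal(out$dropped, c("f2", "f3"))

  ties <- data.frame(feature = paste0("g", 1:4),
                     importance = rep(0.25, 4))
  expect_equal(filter_and_rank(ties, 0.005)$kept, paste0("g", 1:4))

  # 122 features with 29 at or below the cut leaves a ranked list of 93
  imp <- c(rep(0.005, 29), seq(0.9, 0.1, length.out = 93))
  big <- data.frame(feature = sprintf("f%03d", 1:122), importance = imp)
  expect_length(filter_and_rank(big, 0.005)$kept, 93L)

  expect_error(filter_and_rank(data.frame(feature = "a",
                                          importance = 0.001), 0.005),
               "threshold")
  # threshold zero keeps exactly the positive-importance features
  expect_equal(sort(filter_and_rank(rep, 0)$kept), c("f1", "f2"))
})

test_that("mode imputation fills from training modes with smallest-value ties", {
  mk <- function(v) structure(list(
    x = data.frame(a = v), y = rep(0:1, length.out = length(v)),
    meta = data.frame(name = "a", kind = "categorical"), spec = NULL),
    class = "cohort_table")

  expect_equal(impute_mode(mk(c(1, 1, 2, NA)))$x$a, c(1, 1, 2, 1))
  expect_equal(impute_mode(mk(c(3, 3, 7, 7, NA)))$x$a, c(3, 3, 7, 7, 3))

  full <- mk(c(2, 2, 5, 5, 5))
  expect_identical(impute_mode(full)$x, full$x)

  # mode estimated on train only, applied to the second table
  test_tab <- mk(c(NA, 9))
  out <- impute_mode(mk(c(4, 4, 8)), list(test_tab))
  expect_equal(out$apply_to[[1L]]$x$a, c(4, 9))

  expect_error(impute_mode(mk(c(NA, NA))), "a")
})

test_that("imputation is idempotent", {
  tab <- generate_cohort(tiny_spec(seed = 8, missing_rate = 0.1))
  once <- impute_mode(tab)
  twice <- impute_mode(once)
  expect_identical(once$x, twice$x)
})

test_that("to_sequence permutes columns without scaling and inverts cleanly", {
  tab <- generate_cohort(tiny_spec(seed = 10))
  nm <- names(tab$x)
  ident <- to_sequence(tab, nm)
  expect_equal(unclass(ident)[, ], as.matrix(tab$x), ignore_attr = TRUE)

  revd <- to_sequence(tab, rev(nm))
  expect_equal(unclass(revd)[, ], as.matrix(tab$x)[, rev(nm)],
               ignore_attr = TRUE)

  ord <- withr::with_seed(1, sample(nm))
  seqm <- to_sequence(tab, ord)
  inv <- match(nm, ord)
  expect_equal(unclass(seqm)[, inv], as.matrix(tab$x), ignore_attr = TRUE)
  # no-scaling invariant: every output cell is an input cell value
  expect_true(all(seqm %in% as.matrix(tab$x)))

  expect_error(to_sequence(tab, c(nm[1], "nope")), "unknown")
  with_na <- tab; with_na$x[1, 1] <- NA
  expect_error(to_sequence(with_na, nm), "impute")
})

test_that("importance rankings serialize to a two-column CSV", {
  tab <- generate_cohort(tiny_spec(seed = 12))
  rk <- filter_and_rank(compute_importance(tab, seed = 12), 0)
  path <- withr::local_tempfile(fileext = ".csv")
  write_importance_csv(rk, path)
  back <- read.csv(path)
  expect_equal(names(back), c("feature", "importance"))
  expect_equal(back$feature, rk$kept)
})
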