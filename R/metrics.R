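#' Multiclass metrics report
#'
#' Computes the confusion matrix and the standard multiclass metrics from
#' true labels and a probability matrix.  Predicted classes are the row
#' argmax (ties toward the lowest class index).  Per-class precision,
#' recall and F1 are aggregated by support-weighted averaging, the
#' convention under which the weighted recall is algebraically identical to
#' the overall accuracy.  AUC is one-vs-rest area under the ROC curve,
#' support-weighted by default.
#'
#' @param y_true Integer labels in `0:(K - 1)`.
#' @param proba Probability matrix (samples x classes), rows summing to 1.
#' @param class_labels Optional class names.
#' @param auc_average `"weighted"` (support-proportional) or `"macro"`.
#' @return An object of class `metrics_report`: list with `overall`
#'   (accuracy, auc, precision, recall, f1), `per_class` (data frame with
#'   support and per-class metrics) and `confusion` (K x K count matrix,
#'   rows = truth, columns = prediction).
#' @export
compute_metrics <- function(y_true, proba, class_labels = NULL,
                            auc_average = c("weighted", "macro")) {
  auc_average <- match.arg(auc_average)
  y_true <- as.integer(y_true)
  proba <- as.matrix(proba)
  if (nrow(proba) != length(y_true))
    stop("'y_true' length must match rows of 'proba'")
  if (any(abs(rowSums(proba) - 1) > 1e-6))
    stop("probability rows must sum to 1")
  K <- ncol(proba)
  if (K < 2L) stop("at least 2 classes required")
  if (is.null(class_labels))
    class_labels <- if (K == 5L) toast_classes
                    else paste0("class", seq_len(K) - 1L)

  pred <- max.col(proba, ties.method = "first") - 1L
  confusion <- matrix(0L, K, K, dimnames = list(truth = class_labels,
                                                prediction = class_labels))
  for (i in seq_along(y_true))
    confusion[y_true[i] + 1L, pred[i] + 1L] <-
      confusion[y_true[i] + 1L, pred[i] + 1L] + 1L

  support <- rowSums(confusion)
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- support - tp
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)

  auc <- rep(NA_real_, K)
  for (c in seq_len(K)) {
    pos <- y_true == c - 1L
    if (any(pos) && any(!pos)) {
      roc <- pROC::roc(response = pos, predictor = proba[, c],
                       levels = c(FALSE, TRUE), direction = "<",
                       quiet = TRUE)
      auc[c] <- as.numeric(roc$auc)
    }
  }

  present <- support > 0
  if (!all(present))
    warning("class(es) absent from y_true excluded from averages: ",
            paste(class_labels[!present], collapse = ", "))
  w <- support[present] / sum(support[present])
  auc_ok <- present & !is.na(auc)
  auc_overall <- if (any(auc_ok)) {
    if (auc_average == "weighted")
      sum(auc[auc_ok] * support[auc_ok]) / sum(support[auc_ok])
    else mean(auc[auc_ok])
  } else NA_real_

  structure(list(
    overall = list(
      accuracy = mean(pred == y_true),
      auc = auc_overall,
      precision = sum(w * precision[present]),
      recall = sum(w * recall[present]),
      f1 = sum(w * f1[present])),
    per_class = data.frame(class = class_labels, support = support,
                           precision = precision, recall = recall,
                           f1 = f1, auc = auc, row.names = NULL,
                           stringsAsFactors = FALSE),
    confusion = confusion), class = "metrics_report")
}

#' Assemble a metrics report from per-class values
#'
#' Builds a `metrics_report` directly from a per-class table (e.g. values
#' printed in a publication) so that paired deltas can be computed with
#' [report_delta()] without re-running a model.
#'
#' @param per_class Data frame with a `class` column and any of
#'   `precision`, `recall`, `f1`, `auc`, `support`.
#' @param overall Optional named list of overall metrics.
#' @return A `metrics_report` (without a confusion matrix).
#' @export
metrics_report <- function(per_class, overall = NULL) {
  stopifnot(is.data.frame(per_class), "class" %in% names(per_class))
  structure(list(overall = overall, per_class = per_class,
                 confusion = NULL), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  if (!is.null(x$overall)) {
    ov <- unlist(x$overall)
    cat("Overall:", paste(sprintf("%s %.4f", names(ov), ov),
                          collapse = "  "), "\n")
  }
  cat("Per class:\n")
  print(x$per_class, digits = digits)
  invisible(x)
}

#' Paired metric deltas between two reports
#'
#' Signed differences (`after` minus `before`), overall and per class, in
#' the style of paired before/after comparison tables: a positive delta is
#' an improvement brought by the second run.
#'
#' @param before,after `metrics_report` objects over the same class set.
#' @return List with `overall` (named numeric deltas, where both reports
#'   carry the metric) and `per_class` (data frame of per-class deltas).
#' @export
report_delta <- function(before, after) {
  stopifnot(inherits(before, "metrics_report"),
            inherits(after, "metrics_report"))
  if (!identical(before$per_class$class, after$per_class$class))
    stop("reports cover different class sets")
  shared <- intersect(intersect(names(before$per_class),
                                names(after$per_class)),
                      c("precision", "recall", "f1", "auc"))
  pc <- data.frame(class = before$per_class$class,
                   stringsAsFactors = FALSE)
  for (m in shared)
    pc[[m]] <- after$per_class[[m]] - before$per_class[[m]]
  ov <- NULL
  if (!is.null(before$overall) && !is.null(after$overall)) {
    keys <- intersect(names(before$overall), names(after$overall))
    ov <- unlist(after$overall[keys]) - unlist(before$overall[keys])
  }
  list(overall = ov, per_class = pc)
}

# idx subset of a cohort_table, preserving metadata.
cohort_subset <- function(table, idx) {
  structure(list(x = table$x[idx, , drop = FALSE], y = table$y[idx],
                 meta = table$meta, spec = table$spec),
            class = "cohort_table")
}

# Fold assignment: stratified round-robin keeps overall fold sizes within 1
# and class proportions as even as integer counts allow.
make_folds <- function(y, k, stratified, seed) {
  n <- length(y)
  with_seed(seed, {
    if (!stratified) {
      return(sample(rep_len(seq_len(k), n)))
    }
    counts <- table(y)
    if (any(counts < k))
      stop("class(es) with fewer than k = ", k, " members: ",
           paste(names(counts)[counts < k], collapse = ", "),
           "; use stratified = FALSE")
    fold <- integer(n)
    offset <- 0L
    for (cl in names(counts)) {
      members <- sample(which(y == as.integer(cl)))
      fold[members] <- ((seq_along(members) - 1L + offset) %% k) + 1L
      offset <- (offset + length(members)) %% k
    }
    fold
  })
}

#' Cross-validated evaluation of the full pipeline
#'
#' Stratified k-fold cross-validation in which the whole preprocessing
#' chain — mode imputation, tree-ensemble importance, threshold filtering
#' and ranking — is fitted inside each training fold and applied to the
#' held-out fold, so no evaluation information leaks into the ranking or
#' the fill values.
#'
#' @param model_factory `function(x, y, seed)` returning a fitted object
#'   whose `predict(object, newdata)` yields a probability matrix; defaults
#'   to [causal_cnn()] with its default variant and loss.
#' @param cohort A `cohort_table`.
#' @param k Number of folds.
#' @param stratified Preserve class proportions per fold (default); errors
#'   when a class has fewer than `k` members.
#' @param seed Seed controlling fold assignment and the per-fold fits.
#' @param threshold Importance cut passed to [filter_and_rank()].
#' @param importance_params Booster settings for [compute_importance()].
#' @return List with `folds` (per-fold `metrics_report`s), `mean`
#'   (fold-averaged report), `assignments` (fold id per row).
#' @export
cross_validate <- function(model_factory = NULL, cohort, k = 10L,
                           stratified = TRUE, seed = 1L,
                           threshold = 0.005,
                           importance_params = list(nrounds = 50L,
                                                    max_depth = 4L,
                                                    eta = 0.3)) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (k < 2L) stop("'k' must be at least 2")
  if (is.null(model_factory))
    model_factory <- function(x, y, seed)
      causal_cnn(x, y, seed = seed)
  fold <- make_folds(cohort$y, k, stratified, seed)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    train <- cohort_subset(cohort, fold != f)
    test <- cohort_subset(cohort, fold == f)
    imp <- impute_mode(train, list(test))
    train <- imp$train; test <- imp$apply_to[[1L]]
    report <- compute_importance(train, params = importance_params,
                                 seed = seed + f)
    ranking <- filter_and_rank(report, threshold)
    xtr <- to_sequence(train, ranking$kept)
    xte <- to_sequence(test, ranking$kept)
    fit <- model_factory(xtr, train$y, seed + f)
    proba <- predict(fit, xte)
    reports[[f]] <- compute_metrics(test$y, proba)
  }
  list(folds = reports, mean = average_reports(reports),
       assignments = fold)
}

# Fold-averaged metrics report: overall metrics and per-class metrics are
# averaged across folds; supports are summed.
average_reports <- function(reports) {
  ov_names <- names(reports[[1L]]$overall)
  ov <- lapply(ov_names, function(m)
    mean(vapply(reports, function(r) r$overall[[m]], numeric(1)),
         na.rm = TRUE))
  names(ov) <- ov_names
  pc <- reports[[1L]]$per_class
  for (m in c("precision", "recall", "f1", "auc")) {
    vals <- vapply(reports, function(r) r$per_class[[m]], numeric(nrow(pc)))
    pc[[m]] <- rowMeans(matrix(vals, nrow = nrow(pc)), na.rm = TRUE)
  }
  pc$support <- rowSums(vapply(reports,
                               function(r) r$per_class$support,
                               numeric(nrow(pc))))
  structure(list(overall = ov, per_class = pc, confusion = NULL),
            class = "metrics_report")
}

#' Write a metrics report to JSON
#'
#' @param report A `metrics_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path) {
  out <- list(overall = report$overall, per_class = report$per_class)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run a comparison-experiment grid
#'
#' Evaluates every combination of architecture variant, loss function and
#' active-learning strategy on one cohort, using a stratified train/test
#' split with fold-internal preprocessing.  All names are validated before
#' any training starts.
#'
#' @param config Named list with elements:
#'   \describe{
#'     \item{cohort}{a `cohort_table`, a [cohort_spec()], or a CSV path}
#'     \item{variants}{character subset of `"V1"`-`"V4"` (default `"V4"`)}
#'     \item{losses}{character subset of the [loss_config()] menu (default
#'       `"kl_focal"`)}
#'     \item{strategies}{list of cycle settings; each entry is `"none"` or
#'       a list with `strategy` and optionally `alpha`, `fraction` (default
#'       `list("none")`)}
#'     \item{epochs, batch_size, seed, threshold, test_fraction}{optional
#'       scalars}
#'     \item{out_dir}{optional directory to write `grid.csv`,
#'       `metrics_*.json` and `confusion_*.csv`}
#'   }
#' @return An `experiment_result`: list with `grid` (one row per cell with
#'   overall metrics) and `reports` (the full `metrics_report`s).
#' @export
run_experiment <- function(config) {
  variants <- config$variants %||% "V4"
  losses <- config$losses %||% "kl_focal"
  strategies <- config$strategies %||% list("none")
  if (length(variants) == 0L || length(losses) == 0L ||
      length(strategies) == 0L)
    stop("empty experiment grid")
  bad <- setdiff(variants, c("V1", "V2", "V3", "V4"))
  if (length(bad)) stop("unknown variant(s): ", paste(bad, collapse = ", "))
  loss_menu <- c("kl_focal", "focal", "cross_entropy", "kl", "mse", "mae",
                 "mape", "msle")
  bad <- setdiff(losses, loss_menu)
  if (length(bad)) stop("unknown loss(es): ", paste(bad, collapse = ", "))
  strat_name <- function(s) if (identical(s, "none")) "none" else s$strategy
  for (s in strategies)
    if (!strat_name(s) %in% c("none", "entropy", "margin", "mixed"))
      stop("unknown strategy: ", strat_name(s))

  cohort <- config$cohort
  if (is.character(cohort)) cohort <- read_cohort_csv(cohort)
  if (inherits(cohort, "cohort_spec")) cohort <- generate_cohort(cohort)
  stopifnot(inherits(cohort, "cohort_table"))

  seed <- config$seed %||% 1L
  epochs <- config$epochs %||% 100L
  batch_size <- config$batch_size %||% 32L
  threshold <- config$threshold %||% 0.005
  test_fraction <- config$test_fraction %||% 0.2

  k_split <- max(2L, round(1 / test_fraction))
  fold <- make_folds(cohort$y, k_split, stratified = TRUE, seed = seed)
  train <- cohort_subset(cohort, fold != 1L)
  test <- cohort_subset(cohort, fold == 1L)
  imp <- impute_mode(train, list(test))
  train <- imp$train; test <- imp$apply_to[[1L]]
  ranking <- filter_and_rank(compute_importance(train, seed = seed),
                             threshold)
  xtr <- to_sequence(train, ranking$kept)
  xte <- to_sequence(test, ranking$kept)

  strat_label <- vapply(strategies, function(s) {
    if (identical(s, "none")) return("none")
    paste0(s$strategy,
           if (!is.null(s$alpha)) paste0("_a", s$alpha),
           if (!is.null(s$fraction)) paste0("_f", s$fraction))
  }, character(1))
  grid <- expand.grid(variant = variants, loss = losses,
                      strategy_id = seq_along(strategies),
                      stringsAsFactors = FALSE)
  grid$strategy <- strat_label[grid$strategy_id]
  reports <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    lc <- loss_config(name = grid$loss[i])
    fit <- causal_cnn(xtr, train$y, variant = grid$variant[i], loss = lc,
                      epochs = epochs, batch_size = batch_size,
                      seed = seed)
    strat <- strategies[[grid$strategy_id[i]]]
    if (!identical(strat, "none")) {
      cc <- cycle_config(strategy = strat$strategy,
                         alpha = strat$alpha %||% 0.3,
                         fraction = strat$fraction %||% 0.5,
                         epochs = epochs, batch_size = batch_size,
                         loss = lc, seed = seed)
      fit <- run_active_cycle(fit, cc)$model
    }
    rep <- compute_metrics(test$y, predict(fit, xte))
    reports[[i]] <- rep
    rows[[i]] <- cbind(grid[i, c("variant", "loss", "strategy"),
                            drop = FALSE],
                       as.data.frame(rep$overall))
  }
  grid_out <- do.call(rbind, rows)
  rownames(grid_out) <- NULL

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(grid_out, file.path(config$out_dir, "grid.csv"),
              row.names = FALSE)
    for (i in seq_len(nrow(grid_out))) {
      tag <- paste(grid_out$variant[i], grid_out$loss[i],
                   grid_out$strategy[i], sep = "_")
      write_metrics_json(reports[[i]],
                         file.path(config$out_dir,
                                   paste0("metrics_", tag, ".json")))
      write.csv(reports[[i]]$confusion,
                file.path(config$out_dir,
                          paste0("confusion_", tag, ".csv")))
    }
  }
  structure(list(grid = grid_out, reports = reports, config = config),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("Experiment grid (", nrow(x$grid), " cells):\n", sep = "")
  print(x$grid, digits = 4)
  invisible(x)
}
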