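#' Gradient-boosted-tree feature importance
#'
#' Fits an XGBoost multiclass model to the cohort and returns per-feature
#' gain importance, normalized to sum to one.  Gain is the conventional
#' ranking signal of boosted trees: the average loss reduction attributed to
#' splits on each feature.  Features never used in a split (including
#' constant columns) receive importance 0.
#'
#' @param table A `cohort_table` (labels required).  Missing cells are
#'   tolerated by the tree ensemble, but the usual pipeline imputes first
#'   with [impute_mode()].
#' @param params List of booster settings; `nrounds`, `max_depth`, `eta`
#'   and any further `xgboost` parameters.
#' @param seed Integer seed; the fit is deterministic given `seed` and
#'   `params` (single-threaded).
#' @return An `importance_report`: data frame with columns `feature` and
#'   `importance`, attributes `method` and `n_rows`.
#' @export
compute_importance <- function(table,
                               params = list(nrounds = 50L, max_depth = 4L,
                                             eta = 0.3),
                               seed = 1L) {
  stopifnot(inherits(table, "cohort_table"))
  y <- table$y
  if (length(unique(y)) < 2L)
    stop("importance is undefined for single-class labels")
  K <- max(y) + 1L
  xm <- as.matrix(table$x)
  nrounds <- params$nrounds %||% 50L
  extra <- params[setdiff(names(params), "nrounds")]
  xgb_params <- c(list(objective = "multi:softprob", num_class = K,
                       nthread = 1L, verbosity = 0L), extra)
  booster <- with_seed(seed, {
    dtrain <- xgboost::xgb.DMatrix(xm, label = y)
    xgboost::xgb.train(params = xgb_params, data = dtrain,
                       nrounds = nrounds, verbose = 0)
  })
  imp <- xgboost::xgb.importance(model = booster)
  gain <- setNames(rep(0, ncol(xm)), colnames(xm))
  gain[imp$Feature] <- imp$Gain
  if (sum(gain) > 0) gain <- gain / sum(gain)
  structure(
    data.frame(feature = names(gain), importance = unname(gain),
               stringsAsFactors = FALSE),
    method = "xgboost gain", n_rows = nrow(xm),
    class = c("importance_report", "data.frame"))
}

#' Drop low-importance features and rank the rest
#'
#' Features with importance at or below `threshold` are dropped; survivors
#' are ordered by non-increasing importance, ties broken by original column
#' order.  With the default threshold of 0.005 this mirrors the registry
#' preprocessing in which 122 recorded items reduce to a ranked list of 93.
#'
#' @param report An `importance_report` from [compute_importance()].
#' @param threshold Importance cut; the drop is inclusive
#'   (`importance <= threshold` is removed).
#' @return List with `kept` (feature names in rank order), `dropped`
#'   (feature names removed) and `importance` (named vector over `kept`).
#' @export
filter_and_rank <- function(report, threshold = 0.005) {
  stopifnot(is.data.frame(report), nrow(report) > 0)
  keep <- report$importance > threshold
  if (!any(keep))
    stop("all ", nrow(report), " features fall at or below threshold ",
         threshold, "; max importance is ", max(report$importance))
  ord <- order(-report$importance[keep])   # stable: ties keep column order
  kept <- report$feature[keep][ord]
  list(kept = kept,
       dropped = report$feature[!keep],
       importance = setNames(report$importance[keep][ord], kept))
}

# Most frequent observed value; ties broken toward the smallest value.
col_mode <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) == 0L) return(NA_real_)
  tab <- table(v)
  as.numeric(names(tab)[which.max(tab)])  # names sorted ascending; which.max
}                                         # returns the first maximum

#' Per-feature modes of a cohort
#'
#' @param train A `cohort_table` or feature data frame.
#' @return Named numeric vector of modes.
#' @export
feature_modes <- function(train) {
  x <- if (inherits(train, "cohort_table")) train$x else train
  vapply(x, col_mode, numeric(1))
}

#' Mode imputation
#'
#' Fills missing cells with the per-feature mode.  The mode is estimated on
#' the training table only and applied to the training table and every table
#' in `apply_to`, so no information leaks from evaluation data into the
#' fill values.  Continuous features use the most frequent observed value;
#' ties are broken toward the smallest value.
#'
#' @param train A `cohort_table` used to estimate the modes.
#' @param apply_to Optional list of further `cohort_table`s to fill with the
#'   training modes.
#' @return If `apply_to` is empty, the imputed training table; otherwise a
#'   list with elements `train` and `apply_to`.
#' @export
impute_mode <- function(train, apply_to = list()) {
  stopifnot(inherits(train, "cohort_table"))
  modes <- feature_modes(train)
  if (anyNA(modes))
    stop("feature(s) entirely missing in training data: ",
         paste(names(modes)[is.na(modes)], collapse = ", "))
  fill <- function(tab) {
    for (j in names(tab$x)) {
      idx <- is.na(tab$x[[j]])
      if (any(idx)) tab$x[[j]][idx] <- modes[[j]]
    }
    tab
  }
  out_train <- fill(train)
  if (length(apply_to) == 0L) return(out_train)
  list(train = out_train, apply_to = lapply(apply_to, fill))
}

#' Convert a cohort to a ranked feature sequence
#'
#' Reorders the feature columns so that position 0 of each patient's
#' sequence holds the most important feature, position 1 the next, and so
#' on — the order in which the causal network reads them.  Values are
#' copied without any scaling.
#'
#' @param table A `cohort_table` with no missing cells.
#' @param ordering Character vector of feature names, most important first
#'   (the `kept` element of [filter_and_rank()]).
#' @return A numeric matrix (patients x ranked features) of class
#'   `ranked_matrix`, with attributes `ordering` and `labels`.
#' @export
to_sequence <- function(table, ordering) {
  stopifnot(inherits(table, "cohort_table"))
  unknown <- setdiff(ordering, names(table$x))
  if (length(unknown))
    stop("unknown feature(s) in ordering: ", paste(unknown, collapse = ", "))
  if (anyNA(table$x[ordering]))
    stop("missing cells present; impute before sequencing")
  m <- as.matrix(table$x[ordering])
  dimnames(m) <- list(NULL, ordering)
  structure(m, ordering = ordering, labels = table$y,
            class = c("ranked_matrix", class(m)))
}

#' Write an importance ranking to CSV
#'
#' Two columns, `feature` and `importance`, in rank order.
#'
#' @param ranking Result of [filter_and_rank()] or an `importance_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_importance_csv <- function(ranking, path) {
  df <- if (is.data.frame(ranking)) {
    ranking[order(-ranking$importance), c("feature", "importance")]
  } else {
    data.frame(feature = names(ranking$importance),
               importance = unname(ranking$importance))
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
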