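#' Configuration of the active-learning cycle
#'
#' Settings for the train / query / append / fine-tune loop.  The defaults
#' follow the single-cycle protocol: mixed uncertainty with trade-off
#' `alpha = 0.3`, the top 50 percent of the pool queried once, fine-tuning
#' from the current weights under the KL-focal loss.
#'
#' @param strategy Query criterion: `"entropy"`, `"margin"` or `"mixed"`.
#' @param alpha Mixed-criterion trade-off in `[0, 1]`.
#' @param fraction Fraction of the pool to append, in (0, 1].
#' @param mixed_variant `"literal"` or `"entropy_full"` (see
#'   [mixed_score()]).
#' @param n_cycles Number of query/append/fine-tune cycles (default 1;
#'   0 returns the model unchanged).
#' @param epochs,batch_size,learning_rate Fine-tuning schedule.
#' @param pool_policy `"self"` (the query pool is the current training
#'   partition; selected samples are re-weighted by duplication) or
#'   `"holdout"` (a withheld pool supplied to [run_active_cycle()]).
#' @param loss A [loss_config()] used for fine-tuning.
#' @param seed Seed for fine-tuning batch shuffling.
#' @return An object of class `cycle_config`.
#' @export
cycle_config <- function(strategy = "mixed", alpha = 0.3, fraction = 0.5,
                         mixed_variant = "literal", n_cycles = 1L,
                         epochs = 100L, batch_size = 32L,
                         learning_rate = 1e-3, pool_policy = "self",
                         loss = loss_config(), seed = 1L) {
  strategy <- match.arg(strategy, c("entropy", "margin", "mixed"))
  pool_policy <- match.arg(pool_policy, c("self", "holdout"))
  if (n_cycles < 0L) stop("'n_cycles' must be non-negative")
  if (alpha < 0 || alpha > 1) stop("'alpha' must lie in [0, 1]")
  structure(list(strategy = strategy, alpha = alpha, fraction = fraction,
                 mixed_variant = mixed_variant, n_cycles = as.integer(n_cycles),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, pool_policy = pool_policy,
                 loss = loss, seed = as.integer(seed)),
            class = "cycle_config")
}

#' Build the query pool for an active cycle
#'
#' Under the default `"self"` policy the pool is the current training
#' partition itself: querying then re-weights the most uncertain patients
#' by duplicating them into the training set.  Under `"holdout"` the pool
#' is a withheld set supplied by the caller.
#'
#' @param x,y Training partition (matrix and labels).
#' @param policy `"self"` or `"holdout"`.
#' @param holdout List with elements `x` and `y` (required for
#'   `"holdout"`).
#' @return List with elements `x` and `y` (rows value-identical to their
#'   source).
#' @export
query_pool <- function(x, y, policy = c("self", "holdout"),
                       holdout = NULL) {
  policy <- match.arg(policy)
  if (policy == "self") {
    if (nrow(x) == 0L) stop("empty training partition")
    return(list(x = x, y = y))
  }
  if (is.null(holdout) || is.null(holdout$x) || nrow(holdout$x) == 0L)
    stop("holdout policy requires a nonempty holdout pool")
  list(x = as.matrix(holdout$x), y = holdout$y)
}

#' Run the active model-adaptation cycle
#'
#' Executes `n_cycles` rounds of QUERY (score the pool with the current
#' model and the configured uncertainty criterion), APPEND (duplicate the
#' selected `floor(fraction * n)` samples into the training set) and
#' FINETUNE (continue training from the current weights under the
#' configured loss).  The model must already be trained (the TRAIN step).
#'
#' @param object A fitted `causal_cnn`.
#' @param config A [cycle_config()].
#' @param holdout Optional holdout pool (list with `x`, `y`) for the
#'   `"holdout"` pool policy.
#' @param eval Optional evaluation set (list with `x`, `y`); when given,
#'   each cycle's report carries metrics before and after fine-tuning.
#' @return List with elements `model` (the updated `causal_cnn`) and
#'   `report` (a `cycle_report`: one entry per cycle with selected indices,
#'   per-class addition counts and rates, training sizes before/after, and
#'   optional metrics).
#' @export
run_active_cycle <- function(object, config = cycle_config(),
                             holdout = NULL, eval = NULL) {
  stopifnot(inherits(object, "causal_cnn"), inherits(config, "cycle_config"))
  if (!object$net$trained) stop("model must be trained before the cycle")
  cycles <- list()
  if (config$n_cycles == 0L)
    return(list(model = object,
                report = structure(list(), class = "cycle_report")))

  base_counts <- tabulate(object$data$y + 1L,
                          nbins = object$net$spec$n_classes)
  for (cy in seq_len(config$n_cycles)) {
    pool <- query_pool(object$data$x, object$data$y,
                       policy = config$pool_policy, holdout = holdout)
    p <- predict_proba(object$net, pool$x)
    us <- uncertainty_scores(p, config$strategy, config$alpha,
                             config$mixed_variant)
    sel <- select_top_fraction(us$scores, us$direction, config$fraction,
                               labels = pool$y)
    metrics_before <- if (!is.null(eval))
      compute_metrics(eval$y, predict_proba(object$net, eval$x),
                      class_labels = object$class_labels)

    size_before <- nrow(object$data$x)
    object$data$x <- rbind(object$data$x, pool$x[sel$selected, , drop = FALSE])
    object$data$y <- c(object$data$y, pool$y[sel$selected])
    object$net <- train_network(object$net, object$data$x, object$data$y,
                                loss = config$loss, epochs = config$epochs,
                                batch_size = config$batch_size,
                                learning_rate = config$learning_rate,
                                seed = config$seed + cy)
    object$history <- object$net$history
    metrics_after <- if (!is.null(eval))
      compute_metrics(eval$y, predict_proba(object$net, eval$x),
                      class_labels = object$class_labels)

    added <- sel$class_counts
    cycles[[cy]] <- list(
      cycle = cy,
      selected = sel$selected,
      addition_counts = added,
      addition_rates = if (all(base_counts > 0))
        addition_rates(added, base_counts),
      size_before = size_before,
      size_after = nrow(object$data$x),
      metrics_before = metrics_before,
      metrics_after = metrics_after)
  }
  list(model = object, report = structure(cycles, class = "cycle_report"))
}

#' @export
print.cycle_report <- function(x, ...) {
  if (length(x) == 0L) {
    cat("Empty cycle report (0 cycles)\n")
    return(invisible(x))
  }
  for (cy in x) {
    cat("Cycle ", cy$cycle, ": training size ", cy$size_before, " -> ",
        cy$size_after, " (+", length(cy$selected), ")\n", sep = "")
    if (!is.null(cy$addition_counts))
      cat("  addition counts:", paste(cy$addition_counts, collapse = "/"),
          if (!is.null(cy$addition_rates))
            paste0(" (rates %: ",
                   paste(cy$addition_rates, collapse = "/"), ")"), "\n")
  }
  invisible(x)
}

#' Serialize a cycle report to JSON
#'
#' @param report A `cycle_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cycle_report <- function(report, path) {
  slim <- lapply(unclass(report), function(cy) {
    cy$metrics_before <- if (!is.null(cy$metrics_before))
      unclass(cy$metrics_before$overall)
    cy$metrics_after <- if (!is.null(cy$metrics_after))
      unclass(cy$metrics_after$overall)
    cy
  })
  jsonlite::write_json(slim, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
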