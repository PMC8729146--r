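#' Entropy uncertainty score
#'
#' Shannon entropy (natural log) of each predicted class distribution:
#' `-sum_j p_j log p_j`.  The most uncertain samples have the highest
#' entropy, so the selection direction is descending; a uniform row over K
#' classes attains the maximum `log K`.
#'
#' @param p Probability matrix (samples x classes), rows summing to 1.
#' @return Numeric vector of per-sample entropies in `[0, log K]`.
#' @export
entropy_score <- function(p) {
  p <- as.matrix(p)
  pl <- ifelse(p > 0, p * log(p), 0)
  -rowSums(pl)
}

#' Margin uncertainty score
#'
#' Difference between the two largest class probabilities of each row.  A
#' small margin means the classifier can barely separate its top two
#' candidate subtypes, so the selection direction is ascending.
#'
#' @param p Probability matrix with at least 2 columns.
#' @return Numeric vector of per-sample margins in `[0, 1]`.
#' @export
margin_score <- function(p) {
  p <- as.matrix(p)
  if (ncol(p) < 2L) stop("margin requires at least 2 classes")
  top2 <- apply(p, 1L, function(r) sort.int(r, decreasing = TRUE)[1:2])
  top2[1L, ] - top2[2L, ]
}

#' Mixed uncertainty score
#'
#' Convex combination, with trade-off `alpha`, of an entropy-derived term
#' and the top-2 margin:
#' `score = alpha * (p1 * log p1) + (1 - alpha) * (p1 - p2)`,
#' where `p1 >= p2` are the two largest probabilities of the row.  Lower
#' scores are more uncertain (ascending selection).  At `alpha = 0` the
#' ranking equals the margin ranking; at `alpha = 1` it ranks by
#' `p1 * log p1` alone.
#'
#' The first term uses only the top-1 probability's contribution to the
#' entropy rather than the full entropy; `variant = "entropy_full"`
#' substitutes the negated full entropy instead.
#'
#' @param p Probability matrix.
#' @param alpha Trade-off in `[0, 1]` (default 0.3).
#' @param variant `"literal"` (top-1 term) or `"entropy_full"`.
#' @return Numeric vector of per-sample mixed scores.
#' @export
mixed_score <- function(p, alpha = 0.3, variant = c("literal",
                                                    "entropy_full")) {
  if (alpha < 0 || alpha > 1) stop("'alpha' must lie in [0, 1]")
  variant <- match.arg(variant)
  p <- as.matrix(p)
  if (ncol(p) < 2L) stop("mixed score requires at least 2 classes")
  top2 <- apply(p, 1L, function(r) sort.int(r, decreasing = TRUE)[1:2])
  p1 <- top2[1L, ]; p2 <- top2[2L, ]
  ent_part <- if (variant == "literal") {
    ifelse(p1 > 0, p1 * log(p1), 0)
  } else {
    -entropy_score(p)
  }
  alpha * ent_part + (1 - alpha) * (p1 - p2)
}

#' Select the most uncertain fraction of a pool
#'
#' Picks the `floor(fraction * n)` samples that are most uncertain under the
#' given selection direction (`"ascending"`: smallest scores first, as for
#' margin and mixed scores; `"descending"`: largest first, as for entropy).
#' Ties are broken toward the smaller index.
#'
#' @param scores Numeric vector of uncertainty scores.
#' @param direction `"ascending"` or `"descending"`.
#' @param fraction Fraction of the pool to select, in (0, 1].
#' @param labels Optional integer labels of the pool, used to report
#'   per-class counts of the selection.
#' @return An object of class `selection_result`: list with `selected`
#'   (indices, most uncertain first), `fraction`, and `class_counts` (when
#'   `labels` given).
#' @export
select_top_fraction <- function(scores, direction = c("ascending",
                                                      "descending"),
                                fraction = 0.5, labels = NULL) {
  direction <- match.arg(direction)
  n <- length(scores)
  if (n == 0L) stop("empty pool")
  if (fraction <= 0 || fraction > 1) stop("'fraction' must lie in (0, 1]")
  m <- floor(fraction * n)
  key <- if (direction == "ascending") scores else -scores
  sel <- order(key, seq_len(n))[seq_len(m)]   # stable: ties by smaller index
  counts <- NULL
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    counts <- tabulate(labels[sel] + 1L, nbins = max(labels) + 1L)
  }
  structure(list(selected = sel, fraction = fraction, n = n,
                 class_counts = counts),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Active selection:", length(x$selected), "of", x$n,
      sprintf("samples (fraction %.2f)\n", x$fraction))
  if (!is.null(x$class_counts))
    cat("  per-class counts:", paste(x$class_counts, collapse = "/"), "\n")
  invisible(x)
}

# Dispatch a strategy name to scores plus its selection direction.
uncertainty_scores <- function(p, strategy, alpha = 0.3,
                               mixed_variant = "literal") {
  switch(strategy,
    entropy = list(scores = entropy_score(p), direction = "descending"),
    margin = list(scores = margin_score(p), direction = "ascending"),
    mixed = list(scores = mixed_score(p, alpha, mixed_variant),
                 direction = "ascending"),
    stop("unknown strategy: ", strategy))
}
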