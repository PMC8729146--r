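#' TOAST subtype labels
#'
#' The five etiologic subtypes of ischemic stroke in the TOAST system:
#' large-artery atherosclerosis, cardioembolism, small-artery occlusion,
#' other determined cause, and undetermined cause.  Class indices run 0-4
#' in this order throughout the package.
#'
#' @format Character vector of length 5.
#' @export
toast_classes <- c("LAA", "CE", "SAO", "OC", "UND")

# Per-class patient counts of the reference cohort (2310 patients).
default_class_counts <- c(LAA = 1290L, CE = 107L, SAO = 550L, OC = 81L,
                          UND = 282L)

#' Specification of a synthetic stroke cohort
#'
#' Describes the shape of a cohort table: the per-class patient counts, the
#' number of features and how many of them carry class signal, the mix of
#' categorical and continuous features, the class-separation scale, and the
#' missing-cell rate.  The defaults emulate a hospital registry of 2310
#' ischemic-stroke patients with 122 recorded items, a 56/5/24/3/12 percent
#' subtype split, and 99.53 percent data integrity (missing rate 0.0047).
#'
#' @param class_counts Integer vector of 5 non-negative per-class counts
#'   (order LAA, CE, SAO, OC, UND).
#' @param n_features Total number of feature columns.
#' @param n_informative Number of features drawn from class-conditional
#'   distributions; the rest are class-independent noise.  Must not exceed
#'   `n_features`.
#' @param categorical_fraction Fraction of features that are categorical
#'   (small integer codes); the rest are continuous.
#' @param effect_size Non-negative class-separation scale.  Continuous
#'   informative features are unit-variance draws whose per-class means are
#'   proportional to `effect_size`; categorical informative features have
#'   class-dependent category probabilities whose log-odds perturbations are
#'   proportional to it.  Zero removes all class signal.
#' @param missing_rate Probability that any feature cell is missing.
#' @param seed Integer seed; regeneration with the same spec is
#'   cell-for-cell identical.
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(class_counts = default_class_counts,
                        n_features = 122L,
                        n_informative = 30L,
                        categorical_fraction = 0.5,
                        effect_size = 1,
                        missing_rate = 0.0047,
                        seed = 1L) {
  class_counts <- as.integer(class_counts)
  if (length(class_counts) < 1L || anyNA(class_counts) ||
      any(class_counts < 0L))
    stop("'class_counts' must be non-negative counts")
  if (n_informative > n_features)
    stop("'n_informative' must not exceed 'n_features'")
  if (missing_rate < 0 || missing_rate > 1)
    stop("'missing_rate' must lie in [0, 1]")
  if (categorical_fraction < 0 || categorical_fraction > 1)
    stop("'categorical_fraction' must lie in [0, 1]")
  if (effect_size < 0) stop("'effect_size' must be non-negative")
  structure(list(
    n_patients = sum(class_counts),
    class_counts = class_counts,
    n_classes = length(class_counts),
    n_features = as.integer(n_features),
    n_informative = as.integer(n_informative),
    categorical_fraction = categorical_fraction,
    effect_size = effect_size,
    missing_rate = missing_rate,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Cohort specification:", x$n_patients, "patients x", x$n_features,
      "features\n")
  cat("  class counts:", paste(x$class_counts, collapse = "/"), "\n")
  cat("  informative features:", x$n_informative,
      " effect size:", x$effect_size,
      " missing rate:", x$missing_rate, "\n")
  invisible(x)
}

#' Generate a synthetic stroke cohort
#'
#' Draws a patient-by-feature table with the statistical structure described
#' by a [cohort_spec()]: exact per-class row counts, a configurable subset of
#' class-informative features, and sparse missingness injected uniformly at
#' random.  Continuous informative features are unit-scale normal draws with
#' per-class location shifts; categorical informative features are
#' multinomial with per-class perturbed category probabilities.
#' Non-informative features carry no class signal.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `cohort_table`: a list with elements
#'   \describe{
#'     \item{x}{data frame of feature values (categoricals as integer
#'       codes, missing cells as `NA`)}
#'     \item{y}{integer class labels in `0:(K-1)`}
#'     \item{meta}{data frame with columns `name`, `kind`
#'       (`"categorical"`/`"continuous"`) and `informative`}
#'     \item{spec}{the generating spec}
#'   }
#' @examples
#' tab <- generate_cohort(cohort_spec(class_counts = c(60, 10, 20, 5, 15),
#'                                    n_features = 12, n_informative = 4,
#'                                    seed = 7))
#' nrow(tab$x)
#' summarize_distribution(tab)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_patients
    p <- spec$n_features
    K <- spec$n_classes
    y <- rep.int(seq_len(K) - 1L, spec$class_counts)
    y <- sample(y)                      # shuffle row order

    n_cat <- round_half_up(spec$categorical_fraction * p)
    kind <- rep("continuous", p)
    if (n_cat > 0) kind[sample.int(p, n_cat)] <- "categorical"
    informative <- rep(FALSE, p)
    if (spec$n_informative > 0)
      informative[sample.int(p, spec$n_informative)] <- TRUE

    x <- matrix(NA_real_, n, p)
    for (j in seq_len(p)) {
      if (kind[j] == "continuous") {
        if (informative[j]) {
          delta <- rnorm(K)             # per-class offsets, fixed per feature
          x[, j] <- rnorm(n, mean = spec$effect_size * delta[y + 1L])
        } else {
          x[, j] <- rnorm(n)
        }
      } else {
        L <- sample(2:4, 1L)
        base <- runif(L, 0.5, 1.5)
        if (informative[j]) {
          z <- matrix(rnorm(K * L), K, L)
          prob <- base * exp(spec$effect_size * z)  # rows: class log-odds
          prob <- prob / rowSums(prob)
          for (c in seq_len(K) - 1L) {
            rows <- which(y == c)
            x[rows, j] <- sample.int(L, length(rows), replace = TRUE,
                                     prob = prob[c + 1L, ]) - 1L
          }
        } else {
          x[, j] <- sample.int(L, n, replace = TRUE,
                               prob = base / sum(base)) - 1L
        }
      }
    }

    if (spec$missing_rate > 0) {
      miss <- runif(n * p) < spec$missing_rate
      x[miss] <- NA_real_
    }

    nm <- sprintf("f%03d", seq_len(p))
    colnames(x) <- nm
    structure(list(
      x = as.data.frame(x),
      y = y,
      meta = data.frame(name = nm, kind = kind, informative = informative,
                        stringsAsFactors = FALSE),
      spec = spec
    ), class = "cohort_table")
  })
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("Cohort table:", nrow(x$x), "patients x", ncol(x$x), "features\n")
  print(summarize_distribution(x))
  invisible(x)
}

#' Per-class counts and rounded percentages of a cohort
#'
#' Tabulates the subtype labels and reports integer percentages, rounded
#' half-up, the convention used in printed cohort tables.
#'
#' @param table A `cohort_table`, or an integer label vector.
#' @return Data frame with columns `class`, `count`, `percent`.
#' @examples
#' summarize_distribution(c(0, 0, 0, 1, 2))
#' @export
summarize_distribution <- function(table) {
  y <- if (inherits(table, "cohort_table")) table$y else as.integer(table)
  if (length(y) == 0L) stop("empty table: no labels to summarize")
  K <- max(y) + 1L
  counts <- tabulate(y + 1L, nbins = K)
  lab <- if (K == 5L) toast_classes else paste0("class", seq_len(K) - 1L)
  data.frame(class = lab,
             count = counts,
             percent = as.integer(round_half_up(100 * counts / sum(counts))),
             stringsAsFactors = FALSE)
}

#' Per-class addition rates
#'
#' Percentage growth of each class when `added` samples join a base cohort:
#' `100 * added / base`, rounded half-up to integers.  Used to report the
#' composition of actively queried patients relative to the initial data.
#'
#' @param added Non-negative per-class counts of added samples.
#' @param base Strictly positive per-class counts of the base cohort.
#' @return Integer vector of percentages.
#' @examples
#' addition_rates(c(545, 47, 400, 49, 159), c(1290, 107, 550, 81, 282))
#' @export
addition_rates <- function(added, base) {
  if (length(added) != length(base))
    stop("'added' and 'base' must have equal length")
  if (any(base <= 0)) stop("all base counts must be strictly positive")
  if (any(added < 0)) stop("added counts must be non-negative")
  as.integer(round_half_up(100 * added / base))
}

#' Write a cohort to CSV
#'
#' One row per patient, feature columns first, final column `toast` holding
#' the integer class index (0-4).  Missing cells are written as empty
#' strings.
#'
#' @param table A `cohort_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(table, path) {
  stopifnot(inherits(table, "cohort_table"))
  df <- cbind(table$x, toast = table$y)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Inverse of [write_cohort_csv()].  Column kinds are taken from `meta` when
#' supplied; otherwise a column is treated as categorical when all its
#' observed values are integer codes with at most 10 distinct levels.
#'
#' @param path CSV file path.
#' @param meta Optional metadata data frame with columns `name` and `kind`.
#' @return A `cohort_table` (with `spec = NULL`).
#' @export
read_cohort_csv <- function(path, meta = NULL) {
  df <- read.csv(path, check.names = FALSE)
  if (!"toast" %in% names(df)) stop("no 'toast' label column in ", path)
  y <- as.integer(df$toast)
  x <- df[setdiff(names(df), "toast")]
  x[] <- lapply(x, as.numeric)
  if (is.null(meta)) {
    kind <- vapply(x, function(v) {
      v <- v[!is.na(v)]
      if (length(v) && all(v == round(v)) && length(unique(v)) <= 10L)
        "categorical" else "continuous"
    }, character(1))
    meta <- data.frame(name = names(x), kind = unname(kind),
                       informative = NA, stringsAsFactors = FALSE)
  }
  structure(list(x = x, y = y, meta = meta, spec = NULL),
            class = "cohort_table")
}
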