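## Stage 2: global description of what changed — outcome prevalence,
## feature-outcome correlation and importance trajectories, and
## outcome-class centroid drift against the baseline chunk.

#' Construct a trajectory table
#'
#' One row per tracked entity (feature, class, ...), one value per chunk.
#' @noRd
new_trajectory_table <- function(entity, chunk_labels, values, statistic,
                                 extra = NULL) {
  values <- as.matrix(values)
  assert(ncol(values) == length(chunk_labels), "series length != chunks")
  rownames(values) <- entity
  colnames(values) <- chunk_labels
  structure(c(list(entity = entity, chunk_labels = chunk_labels,
                   values = values, statistic = statistic), extra),
            class = "trajectory_table")
}

#' @export
print.trajectory_table <- function(x, ...) {
  cat(sprintf("<trajectory_table> statistic: %s (%d entities x %d chunks)\n",
              x$statistic, nrow(x$values), ncol(x$values)))
  print(signif(x$values, 4))
  invisible(x)
}

#' @export
as.data.frame.trajectory_table <- function(x, ...) {
  data.frame(statistic = x$statistic,
             entity = rep(x$entity, times = length(x$chunk_labels)),
             chunk = rep(x$chunk_labels, each = length(x$entity)),
             value = as.vector(x$values), stringsAsFactors = FALSE)
}

#' Outcome prevalence per temporal chunk
#'
#' Fraction of patients with the outcome category, per chunk, with
#' denominators.
#'
#' @param dataset a `chunked_dataset`.
#' @param outcome_category category of interest (e.g. `"deceased"`).
#' @return A `trajectory_table` (statistic `"prevalence"`); per-chunk
#'   denominators in `$denominators`. Empty chunks yield `NA`.
#' @export
outcome_prevalence_over_time <- function(dataset,
                                         outcome_category = "deceased") {
  stopifnot(inherits(dataset, "chunked_dataset"))
  assert(outcome_category %in% dataset$outcome_levels,
         "unknown outcome category: ", outcome_category)
  p <- dataset$patients
  denom <- vapply(dataset$chunks, function(ch) sum(p$chunk == ch),
                  numeric(1))
  prev <- vapply(dataset$chunks, function(ch) {
    n <- sum(p$chunk == ch)
    if (n == 0) NA_real_ else
      sum(p$chunk == ch & p$outcome == outcome_category) / n
  }, numeric(1))
  new_trajectory_table(outcome_category, dataset$chunks,
                       matrix(prev, nrow = 1), "prevalence",
                       extra = list(denominators = denom))
}

#' Feature-outcome correlation per temporal chunk
#'
#' Point-biserial Pearson (or Spearman) correlation between each feature
#' and the binary outcome indicator (1 = category of interest), computed
#' within each chunk. A feature constant within a chunk yields `NA`, not 0.
#'
#' @param dataset a `chunked_dataset`.
#' @param features feature names (low mode: attribute columns; high mode:
#'   event tokens, as presence indicators). Default: all numeric
#'   attributes (low) or the 20 most frequent tokens (high).
#' @param outcome_category positive category.
#' @param method `"pearson"` or `"spearman"`.
#' @return A `trajectory_table`.
#' @export
correlation_over_time <- function(dataset, features = NULL,
                                  outcome_category = "deceased",
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(dataset, "chunked_dataset"))
  mat <- characterization_matrix(dataset)
  if (is.null(features)) {
    features <- if (dataset$mode == "low") {
      numeric_feature_names(dataset)
    } else {
      names(sort(colSums(mat), decreasing = TRUE))[
        seq_len(min(20L, ncol(mat)))]
    }
  }
  missing_f <- setdiff(features, colnames(mat))
  assert(length(missing_f) == 0, "unknown features: ",
         paste(missing_f, collapse = ", "))
  y <- as.numeric(dataset$patients$outcome == outcome_category)
  vals <- sapply(dataset$chunks, function(ch) {
    rows <- dataset$patients$chunk == ch
    vapply(features, function(f) {
      xf <- mat[rows, f]
      if (stats::sd(xf) == 0 || stats::sd(y[rows]) == 0) return(NA_real_)
      stats::cor(xf, y[rows], method = method)
    }, numeric(1))
  })
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
  new_trajectory_table(features, dataset$chunks, vals, method)
}

#' Tree-ensemble feature importance per temporal chunk
#'
#' Fits a seeded random forest per chunk (outcome category vs rest) and
#' reports normalized importances (summing to 1 within each chunk).
#' Single-class chunks are skipped with a warning (`NA` column).
#'
#' @param dataset a `chunked_dataset`.
#' @param outcome_category positive category.
#' @param features optional feature subset (as in
#'   [correlation_over_time()]).
#' @param n_trees,max_depth forest size.
#' @param importance `"impurity"` or `"permutation"`.
#' @param seed RNG seed (per-chunk seeds derived from it).
#' @return A `trajectory_table` (statistic `"importance"`).
#' @export
feature_importance_over_time <- function(dataset,
                                         outcome_category = "deceased",
                                         features = NULL, n_trees = 50L,
                                         max_depth = 3L,
                                         importance = c("impurity",
                                                        "permutation"),
                                         seed = 1L) {
  importance <- match.arg(importance)
  stopifnot(inherits(dataset, "chunked_dataset"))
  mat <- characterization_matrix(dataset)
  if (!is.null(features)) {
    missing_f <- setdiff(features, colnames(mat))
    assert(length(missing_f) == 0, "unknown features: ",
           paste(missing_f, collapse = ", "))
    mat <- mat[, features, drop = FALSE]
  }
  y <- as.numeric(dataset$patients$outcome == outcome_category)
  vals <- sapply(dataset$chunks, function(ch) {
    rows <- dataset$patients$chunk == ch
    if (length(unique(y[rows])) < 2) {
      warning("single-class chunk skipped: ", ch)
      return(rep(NA_real_, ncol(mat)))
    }
    fit <- rf_fit(mat[rows, , drop = FALSE], y[rows], n_trees = n_trees,
                  max_depth = max_depth,
                  seed = derive_seed(seed, paste0("rf", ch)))
    rf_importance(fit, type = importance, x = mat[rows, , drop = FALSE],
                  y = y[rows], seed = derive_seed(seed, paste0("pi", ch)))
  })
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
  new_trajectory_table(colnames(mat), dataset$chunks, vals, "importance")
}

#' Outcome-class centroid drift against the reference chunk
#'
#' For each chunk and each group (every outcome class, plus the overall
#' population), the cosine distance between the group's centroid in that
#' chunk and the same group's centroid in the reference chunk, on the
#' one-hot bag-of-events (high mode) or one-hot-encoded attribute (low
#' mode, after discretization) representation. The reference chunk's
#' values are 0; a group empty in a chunk yields `NA`.
#'
#' @param dataset a `chunked_dataset`.
#' @param n_bins discretization bins for low-granularity cohorts.
#' @return A `trajectory_table` (statistic `"centroid_cosine_distance"`)
#'   with one row per outcome class plus `"overall"`.
#' @export
class_centroid_drift <- function(dataset, n_bins = 5L) {
  stopifnot(inherits(dataset, "chunked_dataset"))
  assert(length(dataset$chunks) >= 2, "need at least 2 chunks")
  if (dataset$mode == "low" && is.null(dataset$events)) {
    dataset <- discretize_continuous(dataset, n_bins = n_bins)
  }
  mat <- bag_of_events(dataset)
  groups <- c(dataset$outcome_levels, "overall")
  p <- dataset$patients
  group_rows <- function(g, ch) {
    sel <- p$chunk == ch & (g == "overall" | p$outcome == g)
    p$patient_id[sel]
  }
  ref_cents <- lapply(groups, function(g) {
    rows <- group_rows(g, dataset$reference_chunk)
    if (!length(rows)) return(NULL)
    centroid(mat[rows, , drop = FALSE])
  })
  names(ref_cents) <- groups
  vals <- sapply(dataset$chunks, function(ch) {
    vapply(groups, function(g) {
      rows <- group_rows(g, ch)
      if (!length(rows) || is.null(ref_cents[[g]])) return(NA_real_)
      if (ch == dataset$reference_chunk) return(0)
      cosine_distance(ref_cents[[g]], centroid(mat[rows, , drop = FALSE]))
    }, numeric(1))
  })
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = length(groups))
  new_trajectory_table(groups, dataset$chunks, vals,
                       "centroid_cosine_distance")
}

#' Top-k entities of a trajectory table
#'
#' Entities ranked by absolute statistic in one chunk (or by the pooled
#' mean over chunks); exact ties broken lexicographically by entity name.
#'
#' @param table a `trajectory_table`.
#' @param k number of entities to return.
#' @param ranking_chunk chunk label, or `"pooled"` (default) for the mean
#'   of absolute values over chunks.
#' @return Character vector of entity names, best first.
#' @export
top_k_trajectories <- function(table, k, ranking_chunk = "pooled") {
  stopifnot(inherits(table, "trajectory_table"))
  assert(k <= length(table$entity), "k exceeds number of entities")
  score <- if (identical(ranking_chunk, "pooled")) {
    rowMeans(abs(table$values), na.rm = TRUE)
  } else {
    assert(ranking_chunk %in% table$chunk_labels,
           "unknown ranking chunk: ", ranking_chunk)
    abs(table$values[, ranking_chunk])
  }
  ord <- order(-score, table$entity)
  table$entity[ord][seq_len(k)]
}

## Feature representation for stage 2: low mode keeps raw numeric columns
## plus categorical dummies; high mode uses event-presence indicators.
characterization_matrix <- function(dataset) {
  feature_matrix(dataset)
}

numeric_feature_names <- function(dataset) {
  f <- dataset$features
  cols <- setdiff(names(f), c("patient_id", "admission_date"))
  cols[vapply(cols, function(cn) is.numeric(f[[cn]]), logical(1))]
}
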