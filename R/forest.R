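## Small seeded random forest (binary classification, Gini impurity),
## written in base R because no tree-ensemble package is available in the
## target library. Scope: impurity and permutation feature importance at
## monitoring scale (hundreds of rows, tens of features); not a general
## learner.

## Best split of one node for one feature: returns cut point and Gini gain.
best_split_feature <- function(x, y1, w_node) {
  o <- order(x)
  xs <- x[o]; ys <- y1[o]
  n <- length(xs)
  if (xs[1] == xs[n]) return(NULL)
  cum1 <- cumsum(ys)
  tot1 <- cum1[n]
  idx <- which(diff(xs) > 0)           # candidate cuts between runs
  if (!length(idx)) return(NULL)
  nl <- idx; nr <- n - nl
  p1l <- cum1[idx] / nl; p1r <- (tot1 - cum1[idx]) / nr
  gini_l <- 2 * p1l * (1 - p1l); gini_r <- 2 * p1r * (1 - p1r)
  p1 <- tot1 / n
  gain <- 2 * p1 * (1 - p1) - (nl / n) * gini_l - (nr / n) * gini_r
  b <- which.max(gain)
  if (gain[b] <= 1e-12) return(NULL)
  list(cut = (xs[idx[b]] + xs[idx[b] + 1]) / 2,
       gain = gain[b] * w_node)
}

predict_tree <- function(tree, x) {
  out <- numeric(nrow(x))
  rec <- function(node, rows) {
    if (!length(rows)) return()
    if (node$leaf) { out[rows] <<- node$pred; return() }
    go_left <- x[rows, node$feature] <= node$cut
    rec(node$left, rows[go_left])
    rec(node$right, rows[!go_left])
  }
  rec(tree, seq_len(nrow(x)))
  out
}

#' Fit a seeded random forest (binary outcome)
#'
#' @param x numeric feature matrix.
#' @param y binary vector (0/1 or logical).
#' @param n_trees,max_depth,min_node,mtry forest hyperparameters
#'   (`mtry` defaults to `floor(sqrt(p))`).
#' @param seed RNG seed; identical seed, identical forest.
#' @return An `rf_model` with per-tree structures, out-of-bag row sets and
#'   accumulated impurity importance.
#' @export
rf_fit <- function(x, y, n_trees = 50L, max_depth = 3L, min_node = 5L,
                   mtry = NULL, seed = 1L) {
  x <- as.matrix(x)
  y1 <- as.numeric(y)
  assert(all(y1 %in% c(0, 1)), "y must be binary 0/1")
  assert(length(unique(y1)) == 2, "y must contain both classes")
  p <- ncol(x)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  n <- nrow(x)
  with_seed(seed, {
    trees <- vector("list", n_trees)
    oob <- vector("list", n_trees)
    imp_env <- new.env()
    imp_env$importance <- setNames(numeric(p),
                                   colnames(x) %||% paste0("f", seq_len(p)))
    for (t in seq_len(n_trees)) {
      boot <- sample.int(n, n, replace = TRUE)
      oob[[t]] <- setdiff(seq_len(n), unique(boot))
      env <- new.env(); env$importance <- numeric(p)
      trees[[t]] <- grow_tree_env(x, y1, boot, max_depth, min_node,
                                  mtry, env)
      imp_env$importance <- imp_env$importance + env$importance
    }
    structure(list(trees = trees, oob = oob,
                   importance_raw = imp_env$importance,
                   feature_names = names(imp_env$importance),
                   n = n, seed = seed),
              class = "rf_model")
  })
}

## Recursive CART growth; split-gain importance is accumulated in `env`
## (R has no by-reference scalars).
grow_tree_env <- function(x, y1, rows, max_depth, min_node, mtry, env) {
  n_total <- length(rows)
  rec <- function(rows, depth) {
    if (depth >= max_depth || length(rows) < 2 * min_node ||
        length(unique(y1[rows])) < 2) {
      return(list(leaf = TRUE, pred = mean(y1[rows])))
    }
    feats <- sample.int(ncol(x), mtry)
    best <- NULL; best_f <- NA_integer_
    for (f in feats) {
      sp <- best_split_feature(x[rows, f], y1[rows],
                               length(rows) / n_total)
      if (!is.null(sp) && (is.null(best) || sp$gain > best$gain)) {
        best <- sp; best_f <- f
      }
    }
    if (is.null(best)) return(list(leaf = TRUE, pred = mean(y1[rows])))
    env$importance[best_f] <- env$importance[best_f] + best$gain
    go_left <- x[rows, best_f] <= best$cut
    left <- rows[go_left]; right <- rows[!go_left]
    if (!length(left) || !length(right)) {
      return(list(leaf = TRUE, pred = mean(y1[rows])))
    }
    list(leaf = FALSE, feature = best_f, cut = best$cut,
         left = rec(left, depth + 1), right = rec(right, depth + 1))
  }
  rec(rows, 0L)
}

#' @export
predict.rf_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  preds <- vapply(object$trees, predict_tree, numeric(nrow(newdata)),
                  x = newdata)
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = nrow(newdata))
  rowMeans(preds)
}

#' Normalized feature importance of a forest
#'
#' @param model an `rf_model`.
#' @param type `"impurity"` (default: accumulated Gini decrease) or
#'   `"permutation"` (out-of-bag accuracy drop when a feature is permuted).
#' @param x,y training data (permutation type only).
#' @param seed permutation seed.
#' @return Named vector summing to 1 (nonnegative values).
#' @export
rf_importance <- function(model, type = c("impurity", "permutation"),
                          x = NULL, y = NULL, seed = 1L) {
  type <- match.arg(type)
  if (type == "impurity") {
    imp <- model$importance_raw
  } else {
    assert(!is.null(x) && !is.null(y), "permutation importance needs x, y")
    x <- as.matrix(x); y1 <- as.numeric(y)
    imp <- setNames(numeric(ncol(x)), model$feature_names)
    with_seed(seed, {
      for (t in seq_along(model$trees)) {
        rows <- model$oob[[t]]
        if (length(rows) < 2) next
        base_acc <- mean((predict_tree(model$trees[[t]],
                                       x[rows, , drop = FALSE]) > 0.5) ==
                           y1[rows])
        for (f in seq_len(ncol(x))) {
          xp <- x[rows, , drop = FALSE]
          xp[, f] <- xp[sample.int(nrow(xp)), f]
          acc <- mean((predict_tree(model$trees[[t]], xp) > 0.5) ==
                        y1[rows])
          imp[f] <- imp[f] + max(base_acc - acc, 0)
        }
      }
    })
  }
  imp <- pmax(imp, 0)
  if (sum(imp) == 0) imp[] <- 1 / length(imp) else imp <- imp / sum(imp)
  imp
}
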