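## Stage 1: drift metrics, signal normalization and threshold flagging.

#' Jensen-Shannon divergence between two frequency distributions
#'
#' `JSD(P, Q) = KL(P || M)/2 + KL(Q || M)/2` with the mixture
#' `M = (P + Q)/2`. Symmetric in its arguments and, in base 2, bounded by 1
#' (the bound is attained by distributions with disjoint support).
#'
#' @param p,q [freq_dist()] objects sharing a vocabulary, or plain
#'   probability vectors of equal length summing to 1.
#' @param base logarithm base; 2 (default) gives the bounded form, use
#'   `exp(1)` for nats.
#' @return Nonnegative scalar.
#' @export
jensen_shannon_divergence <- function(p, q, base = 2) {
  pv <- as_prob(p); qv <- as_prob(q)
  if (inherits(p, "freq_dist") && inherits(q, "freq_dist")) {
    assert(identical(p$vocabulary, q$vocabulary),
           "p and q are defined over different vocabularies")
  }
  assert(length(pv) == length(qv), "p and q have different lengths")
  assert(abs(sum(pv) - 1) < 1e-6 && abs(sum(qv) - 1) < 1e-6,
         "inputs must be normalized probability vectors")
  assert(all(pv >= 0) && all(qv >= 0), "negative probabilities")
  m <- (pv + qv) / 2
  0.5 * kl_div(pv, m, base) + 0.5 * kl_div(qv, m, base)
}

as_prob <- function(x) {
  if (inherits(x, "freq_dist")) x$probabilities else as.numeric(x)
}

## KL(p || m) with 0 log 0 = 0; m > 0 wherever p > 0 by mixture construction.
kl_div <- function(p, m, base) {
  i <- p > 0
  sum(p[i] * (log(p[i] / m[i]) / log(base)))
}

#' Elementwise arithmetic mean of a set of vectors
#'
#' @param vectors numeric matrix (rows = vectors) or list of equal-length
#'   numeric vectors.
#' @return The centroid vector.
#' @export
centroid <- function(vectors) {
  if (is.list(vectors)) {
    assert(length(vectors) > 0, "empty collection")
    lens <- lengths(vectors)
    assert(all(lens == lens[1]), "vectors of unequal length")
    vectors <- do.call(rbind, vectors)
  }
  assert(is.matrix(vectors) && nrow(vectors) > 0, "empty collection")
  colMeans(vectors)
}

#' Cosine distance between two vectors
#'
#' `1 - u.v / (|u| |v|)`, in `[0, 2]`.
#'
#' @param u,v numeric vectors of equal length with nonzero norm.
#' @return Scalar distance.
#' @export
cosine_distance <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  assert(nu > 0 && nv > 0, "cosine distance undefined for zero-norm vector")
  1 - sum(u * v) / (nu * nv)
}

cosine_similarity <- function(u, v) 1 - cosine_distance(u, v)

#' Construct a drift signal series
#'
#' One value per chunk (reference chunk included with its self-comparison
#' value), plus the min-max normalized series.
#' @noRd
new_drift_signal <- function(metric_name, chunk_labels, raw_values,
                             reference_chunk, threshold_policy = NULL) {
  structure(list(metric_name = metric_name,
                 chunk_labels = chunk_labels,
                 raw_values = as.numeric(raw_values),
                 normalized_values = normalize_signal(raw_values),
                 reference_chunk = reference_chunk,
                 flags = rep(FALSE, length(raw_values)),
                 threshold_policy = threshold_policy),
            class = "drift_signal")
}

#' @export
print.drift_signal <- function(x, ...) {
  cat(sprintf("<drift_signal> %s (reference: %s)\n", x$metric_name,
              x$reference_chunk))
  print(data.frame(chunk = x$chunk_labels, raw = signif(x$raw_values, 4),
                   normalized = signif(x$normalized_values, 4),
                   flagged = x$flags))
  invisible(x)
}

#' @export
as.data.frame.drift_signal <- function(x, ...) {
  data.frame(metric = x$metric_name, chunk = x$chunk_labels,
             raw = x$raw_values, normalized = x$normalized_values,
             flagged = x$flags, stringsAsFactors = FALSE)
}

#' Min-max normalization of a drift signal series
#'
#' `(X - min X) / (max X - min X)`; a constant series maps to all zeros
#' (the no-variation convention).
#'
#' @param raw numeric series.
#' @return Series in `[0, 1]`.
#' @export
normalize_signal <- function(raw) {
  raw <- as.numeric(raw)
  assert(length(raw) > 0, "empty series")
  rng <- range(raw)
  if (rng[2] > rng[1]) (raw - rng[1]) / (rng[2] - rng[1]) else rep(0, length(raw))
}

## Resolve the comparison pairs: each chunk vs the reference (default) or
## each chunk vs its predecessor.
other_chunks <- function(dataset, comparison) {
  if (comparison == "reference") {
    list(ref = rep(dataset$reference_chunk, length(dataset$chunks)),
         tgt = dataset$chunks)
  } else {
    list(ref = c(dataset$chunks[1], head(dataset$chunks, -1)),
         tgt = dataset$chunks)
  }
}

#' Jensen-Shannon drift signal over chunks
#'
#' Per chunk, the JSD between that chunk's smoothed token distribution and
#' the reference chunk's (or the preceding chunk's). Low-granularity
#' cohorts are tokenized with [discretize_continuous()] first.
#'
#' @param dataset a `chunked_dataset`.
#' @param epsilon additive smoothing per vocabulary cell.
#' @param base logarithm base.
#' @param comparison `"reference"` (default) or `"consecutive"`.
#' @param per_patient count patient indicators instead of occurrences.
#' @param n_bins bins for low-granularity discretization.
#' @return A `drift_signal`.
#' @export
jsd_signal <- function(dataset, epsilon = 0.5, base = 2,
                       comparison = c("reference", "consecutive"),
                       per_patient = FALSE, n_bins = 5L) {
  comparison <- match.arg(comparison)
  if (dataset$mode == "low" && is.null(dataset$events)) {
    dataset <- discretize_continuous(dataset, n_bins = n_bins)
  }
  fr <- chunk_frequencies(dataset, epsilon = epsilon,
                          per_patient = per_patient)
  pairs <- other_chunks(dataset, comparison)
  vals <- mapply(function(r, t) {
    jensen_shannon_divergence(fr[[r]], fr[[t]], base = base)
  }, pairs$ref, pairs$tgt)
  new_drift_signal("jsd", dataset$chunks, vals, dataset$reference_chunk)
}

#' Centroid cosine distance drift signal
#'
#' Per chunk, the cosine distance between that chunk's centroid and the
#' reference chunk's centroid of the one-hot bag-of-events (high mode) or
#' the standardized feature representation (low mode).
#'
#' @inheritParams jsd_signal
#' @return A `drift_signal` (reference chunk's own value is 0).
#' @export
centroid_cosine_signal <- function(dataset,
                                   comparison = c("reference",
                                                  "consecutive")) {
  comparison <- match.arg(comparison)
  assert(length(dataset$chunks) >= 2, "need at least 2 chunks")
  mat <- feature_matrix(dataset)
  cents <- lapply(dataset$chunks, function(ch) {
    centroid(mat[chunk_rows(dataset, ch), , drop = FALSE])
  })
  names(cents) <- dataset$chunks
  pairs <- other_chunks(dataset, comparison)
  vals <- mapply(function(r, t) {
    if (r == t) 0 else cosine_distance(cents[[r]], cents[[t]])
  }, pairs$ref, pairs$tgt)
  new_drift_signal("centroid", dataset$chunks, vals,
                   dataset$reference_chunk)
}

#' PCA reconstruction error drift signal
#'
#' Fits a principal-component basis on the reference chunk only (centering,
#' and scaling for low-granularity features, learned on the reference) and
#' scores every chunk by the mean squared norm of the residual after
#' projecting its rows onto that basis. The reference chunk's own value is
#' its in-sample residual.
#'
#' @param dataset a `chunked_dataset`.
#' @param n_components integer number of components, or a fraction in
#'   (0, 1): the smallest basis explaining that share of the reference
#'   variance. Default 0.9.
#' @param scale. standardize columns by reference-chunk standard deviation
#'   (default: yes for low granularity, no for one-hot events).
#' @return A `drift_signal`.
#' @export
pca_reconstruction_signal <- function(dataset, n_components = 0.9,
                                      scale. = NULL) {
  mat <- feature_matrix(dataset)
  if (is.null(scale.)) scale. <- dataset$mode == "low"
  ref <- mat[chunk_rows(dataset, dataset$reference_chunk), , drop = FALSE]
  ctr <- colMeans(ref)
  scl <- if (scale.) {
    s <- apply(ref, 2, stats::sd); s[s == 0] <- 1; s
  } else {
    rep(1, ncol(ref))
  }
  refs <- sweep(sweep(ref, 2, ctr), 2, scl, "/")
  sv <- svd(refs)
  pos <- sv$d > max(sv$d) * 1e-10
  rank <- sum(pos)
  k <- if (n_components < 1) {
    var_expl <- cumsum(sv$d^2) / sum(sv$d^2)
    min(which(var_expl >= n_components))
  } else {
    assert(n_components <= rank,
           "n_components (", n_components, ") exceeds reference rank (",
           rank, ")")
    as.integer(n_components)
  }
  V <- sv$v[, seq_len(k), drop = FALSE]
  vals <- vapply(dataset$chunks, function(ch) {
    x <- mat[chunk_rows(dataset, ch), , drop = FALSE]
    xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
    resid <- xs - (xs %*% V) %*% t(V)
    mean(rowSums(resid^2))
  }, numeric(1))
  sig <- new_drift_signal("pca", dataset$chunks, vals,
                          dataset$reference_chunk)
  sig$n_components <- k
  sig
}

#' Autoencoder reconstruction error drift signal
#'
#' Trains a single-hidden-layer autoencoder on the reference chunk
#' (centering/scaling learned on the reference) and scores every chunk by
#' its mean squared reconstruction error. Fixed seed and single-threaded
#' training make the series reproducible.
#'
#' @param dataset a `chunked_dataset`.
#' @param bottleneck hidden layer width.
#' @param epochs full-batch Adam epochs.
#' @param lr learning rate.
#' @param activation `"relu"` (default) or `"linear"` (a linear
#'   autoencoder converges to the PCA subspace).
#' @param seed RNG seed for weight initialization.
#' @param scale. as in [pca_reconstruction_signal()].
#' @return A `drift_signal`.
#' @export
autoencoder_reconstruction_signal <- function(dataset, bottleneck = 16L,
                                              epochs = 200L, lr = 0.01,
                                              activation = c("relu",
                                                             "linear"),
                                              seed = 1L, scale. = NULL) {
  activation <- match.arg(activation)
  mat <- feature_matrix(dataset)
  if (is.null(scale.)) scale. <- dataset$mode == "low"
  ref <- mat[chunk_rows(dataset, dataset$reference_chunk), , drop = FALSE]
  ctr <- colMeans(ref)
  scl <- if (scale.) {
    s <- apply(ref, 2, stats::sd); s[s == 0] <- 1; s
  } else {
    rep(1, ncol(ref))
  }
  refs <- sweep(sweep(ref, 2, ctr), 2, scl, "/")
  model <- ae_train(refs, bottleneck = bottleneck, epochs = epochs,
                    lr = lr, activation = activation, seed = seed)
  vals <- vapply(dataset$chunks, function(ch) {
    x <- mat[chunk_rows(dataset, ch), , drop = FALSE]
    xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
    mean(rowSums((xs - ae_predict(model, xs))^2))
  }, numeric(1))
  sig <- new_drift_signal("autoencoder", dataset$chunks, vals,
                          dataset$reference_chunk)
  sig$training <- model$meta
  sig
}

#' Two-chunk classifier separability drift signal
#'
#' For each chunk, labels reference rows 0 and target rows 1 and reports
#' the cross-validated balanced accuracy of a seeded ridge-regularized
#' logistic classifier: about 0.5 when the chunks are exchangeable (no
#' drift), 1 when fully separable. The reference chunk's own entry is the
#' balanced accuracy of separating a random split of the reference against
#' itself (also about 0.5).
#'
#' @param dataset a `chunked_dataset`.
#' @param cv_folds stratified cross-validation folds.
#' @param lambda ridge penalty passed to glmnet.
#' @param seed RNG seed controlling fold assignment and the self-split.
#' @return A `drift_signal`.
#' @export
classifier_error_signal <- function(dataset, cv_folds = 5L, lambda = 0.01,
                                    seed = 1L) {
  assert(length(dataset$chunks) >= 2, "need at least 2 chunks")
  mat <- feature_matrix(dataset)
  if (dataset$mode == "low") {
    ctr <- colMeans(mat); s <- apply(mat, 2, stats::sd); s[s == 0] <- 1
    mat <- sweep(sweep(mat, 2, ctr), 2, s, "/")
  }
  ref_rows <- chunk_rows(dataset, dataset$reference_chunk)
  vals <- vapply(seq_along(dataset$chunks), function(i) {
    ch <- dataset$chunks[[i]]
    if (ch == dataset$reference_chunk) {
      x <- mat[ref_rows, , drop = FALSE]
      y <- with_seed(derive_seed(seed, paste0("self", ch)), {
        sample(rep(0:1, length.out = nrow(x)))
      })
    } else {
      tgt_rows <- chunk_rows(dataset, ch)
      x <- mat[c(ref_rows, tgt_rows), , drop = FALSE]
      y <- c(rep(0L, length(ref_rows)), rep(1L, length(tgt_rows)))
    }
    cv_balanced_accuracy(x, y, cv_folds = cv_folds, lambda = lambda,
                         seed = derive_seed(seed, paste0("cv", ch)))
  }, numeric(1))
  new_drift_signal("classifier", dataset$chunks, vals,
                   dataset$reference_chunk)
}

## Stratified K-fold CV balanced accuracy of a ridge logistic model.
cv_balanced_accuracy <- function(x, y, cv_folds = 5L, lambda = 0.01,
                                 seed = 1L) {
  assert(min(table(y)) >= cv_folds,
         "each class needs at least cv_folds rows")
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(cv_folds), length(idx))
    }
  })
  accs <- vapply(seq_len(cv_folds), function(f) {
    tr <- folds != f; te <- !tr
    if (length(unique(y[tr])) < 2 || length(unique(y[te])) < 2) {
      warning("degenerate single-class fold skipped")
      return(NA_real_)
    }
    fit <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr],
                          family = "binomial", alpha = 0,
                          lambda = lambda, standardize = FALSE)
    p <- as.numeric(stats::predict(fit, x[te, , drop = FALSE],
                                   type = "response"))
    yhat <- as.integer(p > 0.5)
    sens <- mean(yhat[y[te] == 1] == 1)
    spec <- mean(yhat[y[te] == 0] == 0)
    (sens + spec) / 2
  }, numeric(1))
  mean(accs, na.rm = TRUE)
}

#' Flag drifting chunks in a signal
#'
#' Sequential k-standard-deviation rule: the first `reference_window`
#' values of the series (the reference chunk's self-comparison included)
#' form the baseline; each later value is flagged when it exceeds
#' `mean + k_sd * SD` of the baseline, and non-flagged values are absorbed
#' into the baseline (flagged values never are). A zero-variance baseline
#' falls back, with a warning, to flagging any value above the baseline
#' mean (plus `fixed_threshold` if given).
#'
#' @param signal a `drift_signal` (or plain numeric series).
#' @param k_sd threshold multiplier (paper-default 2).
#' @param reference_window number of leading values forming the initial
#'   baseline; `NULL` (default) uses `min(3, length - 1)`.
#' @param fixed_threshold absolute margin used by the zero-variance
#'   fallback (default 0: any increase flags).
#' @return The `drift_signal` with `$flags` filled (for numeric input, the
#'   logical flag vector). Flagged chunk labels are in
#'   `attr(, "flagged_chunks")`.
#' @export
detect_drift <- function(signal, k_sd = 2, reference_window = NULL,
                         fixed_threshold = 0) {
  raw <- if (inherits(signal, "drift_signal")) signal$raw_values else
    as.numeric(signal)
  n <- length(raw)
  if (is.null(reference_window)) reference_window <- min(3L, n - 1L)
  assert(reference_window >= 1L, "signal too short to window")
  assert(n >= reference_window + 1L,
         "signal needs at least reference_window + 1 values")
  baseline <- raw[seq_len(reference_window)]
  flags <- rep(FALSE, n)
  warned <- FALSE
  for (i in (reference_window + 1L):n) {
    s <- stats::sd(baseline)
    thr <- if (s > 0) {
      mean(baseline) + k_sd * s
    } else {
      if (!warned) {
        warning("zero-variance baseline: falling back to fixed threshold")
        warned <- TRUE
      }
      mean(baseline) + fixed_threshold + 1e-12
    }
    if (raw[i] > thr) {
      flags[i] <- TRUE
    } else {
      baseline <- c(baseline, raw[i])
    }
  }
  if (inherits(signal, "drift_signal")) {
    signal$flags <- flags
    signal$threshold_policy <- list(k_sd = k_sd,
                                    reference_window = reference_window,
                                    fixed_threshold = fixed_threshold)
    attr(signal, "flagged_chunks") <- signal$chunk_labels[flags]
    signal
  } else {
    structure(flags, flagged_chunks = which(flags))
  }
}

#' Run all five detection metrics on a cohort
#'
#' @param dataset a `chunked_dataset`.
#' @param metrics subset of
#'   `c("jsd", "centroid", "pca", "autoencoder", "classifier")`.
#' @param seed seed shared by the stochastic metrics.
#' @param k_sd,reference_window flagging policy (see [detect_drift()]).
#' @param ... forwarded to the individual signal constructors.
#' @return Named list of flagged `drift_signal`s.
#' @export
detect_all <- function(dataset,
                       metrics = c("jsd", "centroid", "pca",
                                   "autoencoder", "classifier"),
                       seed = 1L, k_sd = 2, reference_window = NULL, ...) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  sigs <- list()
  for (m in metrics) {
    sigs[[m]] <- switch(m,
      jsd = jsd_signal(dataset, ...),
      centroid = centroid_cosine_signal(dataset),
      pca = pca_reconstruction_signal(dataset),
      autoencoder = autoencoder_reconstruction_signal(
        dataset, seed = derive_seed(seed, "ae")),
      classifier = classifier_error_signal(
        dataset, seed = derive_seed(seed, "clf")))
    sigs[[m]] <- detect_drift(sigs[[m]], k_sd = k_sd,
                              reference_window = reference_window)
  }
  sigs
}
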