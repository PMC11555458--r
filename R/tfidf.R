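## Syntactic comparator to the semantic step: TF-IDF patient vectors,
## spectral clustering with silhouette-based model selection.

#' TF-IDF matrix over patients
#'
#' Patient = document, event token = term. `tf` is the within-patient
#' occurrence count; `idf(t) = log((1 + N) / (1 + df(t))) + 1` (smooth
#' variant, minimal value 1 for a term present in every document). Rows
#' are L2-normalized.
#'
#' @param dataset a `chunked_dataset` with events (snapshot cohorts are
#'   discretized first).
#' @param n_bins discretization bins for snapshot cohorts.
#' @return Numeric matrix patients x tokens; the idf vector is attached as
#'   attribute `"idf"`.
#' @export
tfidf_matrix <- function(dataset, n_bins = 5L) {
  stopifnot(inherits(dataset, "chunked_dataset"))
  if (dataset$mode == "low" && is.null(dataset$events)) {
    dataset <- discretize_continuous(dataset, n_bins = n_bins)
  }
  tf <- bag_of_events(dataset, binary = FALSE)
  n_doc <- nrow(tf)
  df <- colSums(tf > 0)
  idf <- log((1 + n_doc) / (1 + df)) + 1
  m <- sweep(tf, 2, idf, "*")
  norms <- sqrt(rowSums(m^2))
  norms[norms == 0] <- 1
  m <- m / norms
  attr(m, "idf") <- idf
  m
}

## Normalized spectral clustering on a nonnegative similarity matrix:
## k smallest eigenvectors of the symmetric normalized Laplacian,
## row-normalized, then seeded k-means.
spectral_cluster <- function(sim, k, seed = 1L) {
  d <- rowSums(sim)
  d[d == 0] <- 1e-12
  dinv <- 1 / sqrt(d)
  lsym <- -sim * tcrossprod(dinv)
  diag(lsym) <- diag(lsym) + 1
  eg <- eigen(lsym, symmetric = TRUE)
  U <- eg$vectors[, ncol(lsym) - seq_len(k) + 1L, drop = FALSE]
  rn <- sqrt(rowSums(U^2)); rn[rn == 0] <- 1
  U <- U / rn
  with_seed(seed, stats::kmeans(U, centers = k, nstart = 10,
                                iter.max = 50)$cluster)
}

#' TF-IDF + spectral-clustering baseline
#'
#' The comparator to the embedding-based semantic step: patients are
#' represented by TF-IDF vectors, clustered spectrally for each k in
#' `k_range` (cosine-similarity affinity), the k with the highest mean
#' silhouette is kept, and the result is summarized by the top-5
#' highest-mean-TF-IDF features per cluster and the relative cluster
#' frequency per chunk.
#'
#' @param dataset a `chunked_dataset`.
#' @param k_range candidate cluster counts (lower bound must be >= 2).
#' @param n_bins discretization bins for snapshot cohorts.
#' @param seed k-means seed.
#' @return List: `k` (selected), `silhouette` (named mean silhouette per
#'   k), `clusters` (named assignment vector), `top_features` (list of
#'   character(5) per cluster), `chunk_frequencies` (cluster x chunk
#'   matrix, columns summing to 1).
#' @export
tfidf_cluster_baseline <- function(dataset, k_range = 2:15, n_bins = 5L,
                                   seed = 1L) {
  stopifnot(inherits(dataset, "chunked_dataset"))
  assert(min(k_range) >= 2, "k_range lower bound must be >= 2")
  m <- tfidf_matrix(dataset, n_bins = n_bins)
  k_range <- k_range[k_range < nrow(m)]
  assert(length(k_range) > 0, "k_range empty after capping at n - 1")
  sim <- tcrossprod(m)              # cosine similarity (rows are unit)
  sim[sim < 0] <- 0
  diss <- stats::as.dist(1 - sim)
  sil <- setNames(numeric(length(k_range)), k_range)
  assigns <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    cl <- spectral_cluster(sim, k, seed = derive_seed(seed, paste0("k", k)))
    assigns[[i]] <- cl
    sil[i] <- if (length(unique(cl)) < 2) -1 else
      mean(cluster::silhouette(cl, diss)[, "sil_width"])
  }
  best <- which.max(sil)
  clusters <- setNames(assigns[[best]], rownames(m))
  k <- k_range[best]
  top_features <- lapply(seq_len(k), function(cl) {
    rows <- clusters == cl
    mu <- colMeans(m[rows, , drop = FALSE])
    names(sort(mu, decreasing = TRUE))[seq_len(min(5L, ncol(m)))]
  })
  chunks <- dataset$chunks
  pat_chunk <- dataset$patients$chunk[
    match(rownames(m), dataset$patients$patient_id)]
  freq <- sapply(chunks, function(ch) {
    tab <- table(factor(clusters[pat_chunk == ch], levels = seq_len(k)))
    n <- sum(tab)
    if (n == 0) rep(NA_real_, k) else as.numeric(tab) / n
  })
  rownames(freq) <- paste0("cluster", seq_len(k))
  list(k = k, silhouette = sil, clusters = clusters,
       top_features = top_features, chunk_frequencies = freq)
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b cluster assignment vectors of equal length.
#' @return ARI in \[-1, 1\]; 1 = identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  assert(length(a) == length(b), "partitions of unequal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n <- comb2(length(a))
  expected <- sum_i * sum_j / n
  maxidx <- (sum_i + sum_j) / 2
  if (maxidx == expected) return(1)
  (sum_ij - expected) / (maxidx - expected)
}
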