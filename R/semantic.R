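## Stage 3: token corpora / patient graphs, skip-gram embeddings with
## chunk-specific outcome tokens, similarity-change ranking, chapter
## aggregation, and the TF-IDF + spectral-clustering comparator.

#' Outcome token for a category and chunk
#'
#' Joins the outcome category and chunk label with the reserved delimiter,
#' e.g. `"deceased@C03"`, so the same outcome in different chunks is a
#' distinct, machine-separable token.
#' @param outcome_category outcome label.
#' @param chunk chunk label.
#' @export
outcome_token <- function(outcome_category, chunk) {
  paste(outcome_category, chunk, sep = OUTCOME_DELIM)
}

#' Build the sequence corpus of an event-level cohort
#'
#' One token sequence per patient: the temporally ordered event tokens
#' followed by that patient's (category, chunk)-specific outcome token.
#' Both outcome categories receive tokens (survivors too), unless
#' `drop_categories` lists categories to leave untagged.
#'
#' @param dataset a high-granularity `chunked_dataset`.
#' @param drop_categories outcome categories whose token is not appended.
#' @return A `token_corpus`: list(sequences, outcome_token_map). Patients
#'   with zero events become outcome-token-only sequences (counted in a
#'   warning).
#' @export
build_sequence_corpus <- function(dataset, drop_categories = character()) {
  stopifnot(inherits(dataset, "chunked_dataset"))
  assert(dataset$mode == "high" || !is.null(dataset$events),
         "sequence corpus needs event tokens")
  p <- dataset$patients
  ev <- dataset$events
  seqs <- split(ev$token, factor(ev$patient_id, levels = p$patient_id))
  n_empty <- sum(lengths(seqs) == 0)
  if (n_empty > 0) {
    warning(n_empty, " patient(s) with zero events included as ",
            "outcome-token-only sequences")
  }
  otok <- ifelse(p$outcome %in% drop_categories, NA_character_,
                 outcome_token(p$outcome, p$chunk))
  sequences <- mapply(function(s, o) {
    if (is.na(o)) s else c(s, o)
  }, seqs, otok, SIMPLIFY = FALSE)
  map <- unique(data.frame(outcome = p$outcome, chunk = p$chunk,
                           token = outcome_token(p$outcome, p$chunk),
                           stringsAsFactors = FALSE))
  map <- map[!map$outcome %in% drop_categories, , drop = FALSE]
  structure(list(sequences = sequences,
                 outcome_token_map = map[order(map$outcome, map$chunk), ]),
            class = "token_corpus")
}

#' @export
print.token_corpus <- function(x, ...) {
  cat(sprintf("<token_corpus> %d sequences, %d outcome tokens\n",
              length(x$sequences), nrow(x$outcome_token_map)))
  invisible(x)
}

#' Discretize a snapshot cohort into attribute tokens
#'
#' Continuous features are histogram-binned into `n_bins` equal-width
#' segments on the pooled cohort range; bin edges are left-closed/
#' right-open with the top bin right-closed, so a value exactly on an
#' interior edge goes to the upper bin. Tokens are `feature=binK`
#' (`feature=value` for categorical attributes).
#'
#' @param dataset a low-granularity `chunked_dataset`.
#' @param n_bins bins per continuous feature (>= 2).
#' @return The dataset with an `$events` table of attribute tokens (one
#'   unordered token per attribute per patient) and bin edges in
#'   `$bin_edges`.
#' @export
discretize_continuous <- function(dataset, n_bins = 5L) {
  stopifnot(inherits(dataset, "chunked_dataset"))
  assert(dataset$mode == "low", "only snapshot cohorts are discretized")
  assert(n_bins >= 2, "n_bins must be >= 2")
  f <- dataset$features
  cols <- setdiff(names(f), c("patient_id", "admission_date"))
  token_cols <- list()
  edges_all <- list()
  for (cn in cols) {
    v <- f[[cn]]
    if (is.numeric(v)) {
      assert(all(is.finite(v)), "non-finite values in feature ", cn)
      rng <- range(v)
      if (rng[1] == rng[2]) {
        warning("feature constant over cohort, single bin: ", cn)
        bins <- rep(0L, length(v))
        edges <- rng
      } else {
        edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
        bins <- findInterval(v, edges, rightmost.closed = TRUE,
                             left.open = FALSE) - 1L
      }
      edges_all[[cn]] <- edges
      token_cols[[cn]] <- sprintf("%s=bin%d", cn, bins)
    } else {
      token_cols[[cn]] <- sprintf("%s=%s", cn, as.character(v))
    }
  }
  events <- data.frame(
    patient_id = rep(f$patient_id, times = length(cols)),
    order = rep(seq_along(cols), each = nrow(f)),
    token = unlist(token_cols, use.names = FALSE),
    stringsAsFactors = FALSE)
  out <- dataset
  out$events <- events[order(match(events$patient_id,
                                   dataset$patients$patient_id),
                             events$order), ]
  rownames(out$events) <- NULL
  out$bin_edges <- edges_all
  out
}

#' Build the bipartite patient-attribute graph of a snapshot cohort
#'
#' One node per patient, per attribute token and per (outcome, chunk)
#' token; an edge links each patient to every attribute token they hold
#' and to the outcome token of their own chunk. The graph is bipartite
#' between patients and tokens; edges are unweighted.
#'
#' @param dataset a tokenized low-granularity `chunked_dataset`
#'   (see [discretize_continuous()]).
#' @return An [igraph::graph] with vertex attributes `name` and `type`
#'   (`TRUE` for token nodes), plus `role` in
#'   `c("patient", "attribute", "outcome")`.
#' @export
build_patient_graph <- function(dataset) {
  stopifnot(inherits(dataset, "chunked_dataset"))
  assert(!is.null(dataset$events),
         "tokenize first with discretize_continuous()")
  p <- dataset$patients
  ev <- dataset$events
  otok <- outcome_token(p$outcome, p$chunk)
  pat_nodes <- paste0("patient:", p$patient_id)
  attr_nodes <- sort(unique(ev$token))
  out_nodes <- sort(unique(otok))
  edges_attr <- rbind(paste0("patient:", ev$patient_id), ev$token)
  edges_out <- rbind(pat_nodes, otok)
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(pat_nodes), name = pat_nodes,
                            type = FALSE, role = "patient")
  g <- igraph::add_vertices(g, length(attr_nodes), name = attr_nodes,
                            type = TRUE, role = "attribute")
  g <- igraph::add_vertices(g, length(out_nodes), name = out_nodes,
                            type = TRUE, role = "outcome")
  g <- igraph::add_edges(g, c(c(edges_attr), c(edges_out)))
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Construct an embedding table
#' @noRd
new_embedding_table <- function(vectors, training_meta) {
  assert(is.matrix(vectors) && !is.null(rownames(vectors)),
         "vectors must be a named matrix")
  structure(list(dimension = ncol(vectors), vectors = vectors,
                 training_meta = training_meta),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table> %d tokens x %d dims (%s)\n",
              nrow(x$vectors), x$dimension,
              x$training_meta$algorithm %||% "sgns"))
  invisible(x)
}

#' Look up one token vector
#' @param embeddings an `embedding_table`.
#' @param token token id.
#' @export
embedding_vector <- function(embeddings, token) {
  assert(token %in% rownames(embeddings$vectors),
         "token not embedded: ", token)
  embeddings$vectors[token, ]
}

#' Train skip-gram embeddings on a token corpus
#'
#' A single skip-gram-with-negative-sampling model is trained on all
#' sequences jointly, so per-chunk outcome tokens share one vector space
#' and are mutually comparable. Training is seeded and single-threaded:
#' identical seed, identical vectors.
#'
#' @param corpus a `token_corpus`, or a plain list of character vectors.
#' @param dim embedding dimension.
#' @param window maximum context window (dynamically shrunk per position,
#'   word2vec-style); the default 10 approximates whole-sequence context
#'   at typical sequence lengths.
#' @param epochs training epochs.
#' @param min_count tokens rarer than this get no vector.
#' @param negative negative samples per positive pair.
#' @param lr initial learning rate (linear decay).
#' @param seed integer seed.
#' @param tail_average return the Polyak average of the weights over the
#'   second half of training (default `TRUE`); reduces SGD noise in
#'   similarity estimates at small corpus sizes.
#' @param sample frequent-token subsampling threshold (word2vec's `t`,
#'   0 disables). Curbs stopword-like domination of the similarity
#'   geometry; the default 0.005 only trims the head of a desk-scale
#'   clinical vocabulary (tokens above 0.5% corpus share), the
#'   scale-appropriate analog of the web-corpus default 1e-3.
#' @return An `embedding_table`.
#' @export
train_sequence_embeddings <- function(corpus, dim = 64L, window = 10L,
                                      epochs = 10L, min_count = 1L,
                                      negative = 10L, lr = 0.025,
                                      seed = 1L, tail_average = TRUE,
                                      sample = 0.005) {
  sequences <- if (inherits(corpus, "token_corpus")) corpus$sequences else
    corpus
  assert(length(sequences) > 0, "empty corpus")
  tok_counts <- table(unlist(sequences, use.names = FALSE))
  vocab <- names(tok_counts)[tok_counts >= min_count]
  assert(length(vocab) > 0, "all tokens below min_count")
  vocab <- sort(vocab)
  enc <- lapply(sequences, function(s) {
    ids <- match(s, vocab)
    as.integer(ids[!is.na(ids)])
  })
  enc <- enc[lengths(enc) > 0]
  fit <- .sgns_train(enc, length(vocab), as.integer(dim),
                     as.integer(window), as.integer(epochs),
                     as.integer(negative), lr, 0.75, as.integer(seed),
                     isTRUE(tail_average), sample)
  mat <- (fit$input + fit$output) / 2
  rownames(mat) <- vocab
  rownames(fit$input) <- rownames(fit$output) <- vocab
  out <- new_embedding_table(mat, list(algorithm = "sgns", dim = dim,
                                       window = window, epochs = epochs,
                                       min_count = min_count,
                                       seed = seed))
  out$input_vectors <- fit$input
  out$output_vectors <- fit$output
  out
}

#' Train node embeddings of a patient graph
#'
#' Generates seeded second-order `(p, q)` random walks from every node and
#' feeds them to the same skip-gram trainer used for sequences. Isolated
#' nodes cannot be walked and are excluded with a warning.
#'
#' @param graph the [build_patient_graph()] output (any undirected igraph
#'   with vertex names works).
#' @param dim,epochs,negative,lr,seed,tail_average,sample as in
#'   [train_sequence_embeddings()] (`sample` defaults to 0 here: random
#'   walks already resample nodes by degree).
#' @param walk_length steps per walk.
#' @param walks_per_node walks started at every node.
#' @param p,q node2vec return / in-out parameters (1, 1 = uniform walk).
#' @param window context window over the walk sequences.
#' @return An `embedding_table` over node names.
#' @export
train_graph_embeddings <- function(graph, dim = 64L, walk_length = 40L,
                                   walks_per_node = 10L, p = 1, q = 1,
                                   window = 5L, epochs = 5L,
                                   negative = 5L, lr = 0.025, seed = 1L,
                                   tail_average = TRUE, sample = 0) {
  stopifnot(igraph::is_igraph(graph))
  nodes <- igraph::V(graph)$name
  assert(!is.null(nodes), "graph vertices must be named")
  deg <- igraph::degree(graph)
  if (any(deg == 0)) {
    warning(sum(deg == 0), " isolated node(s) excluded from embedding")
  }
  el <- igraph::as_edgelist(graph, names = FALSE)
  assert(nrow(el) > 0, "graph has no edges")
  walks <- .node2vec_walks(t(el), length(nodes),
                           as.integer(walks_per_node),
                           as.integer(walk_length), p, q,
                           as.integer(seed))
  walk_list <- lapply(seq_len(nrow(walks)), function(i) {
    w <- walks[i, ]
    w[w > 0L]
  })
  walk_list <- walk_list[lengths(walk_list) > 1]
  fit <- .sgns_train(walk_list, length(nodes), as.integer(dim),
                     as.integer(window), as.integer(epochs),
                     as.integer(negative), lr, 0.75,
                     as.integer(derive_seed(seed, "sgns")),
                     isTRUE(tail_average), sample)
  mat <- (fit$input + fit$output) / 2
  rownames(mat) <- nodes
  mat <- mat[deg > 0, , drop = FALSE]
  new_embedding_table(mat, list(algorithm = "node2vec-sgns", dim = dim,
                                walk_length = walk_length,
                                walks_per_node = walks_per_node,
                                p = p, q = q, window = window,
                                epochs = epochs, seed = seed))
}

#' Rank tokens by change in similarity to an outcome over time
#'
#' For every token, `delta = cos(token, outcome@last) -
#' cos(token, outcome@first)`: positive deltas mean the token has become
#' more similar to the outcome between the first and last chunk. Sorted
#' descending, ties broken by token id.
#'
#' @param embeddings an `embedding_table` trained jointly over all chunks.
#' @param outcome_category outcome label (e.g. `"deceased"`).
#' @param first_chunk,last_chunk chunk labels being compared.
#' @param tokens tokens to score (default: every embedded token that is
#'   not an outcome token).
#' @param chapter_map optional named token-to-chapter vector carried into
#'   the result.
#' @return data.frame with columns token_id, chapter, sim_first, sim_last,
#'   delta, direction.
#' @export
similarity_change <- function(embeddings, outcome_category, first_chunk,
                              last_chunk, tokens = NULL,
                              chapter_map = NULL) {
  stopifnot(inherits(embeddings, "embedding_table"))
  tok_first <- outcome_token(outcome_category, first_chunk)
  tok_last <- outcome_token(outcome_category, last_chunk)
  for (tk in c(tok_first, tok_last)) {
    assert(tk %in% rownames(embeddings$vectors),
           "outcome token not embedded (chunk missing?): ", tk)
  }
  if (is.null(tokens)) {
    tokens <- setdiff(rownames(embeddings$vectors),
                      grep(OUTCOME_DELIM, rownames(embeddings$vectors),
                           fixed = TRUE, value = TRUE))
  }
  missing_t <- setdiff(tokens, rownames(embeddings$vectors))
  assert(length(missing_t) == 0, "tokens not embedded: ",
         paste(utils::head(missing_t, 5), collapse = ", "))
  vf <- embeddings$vectors[tok_first, ]
  vl <- embeddings$vectors[tok_last, ]
  sim_first <- vapply(tokens, function(t)
    cosine_similarity(embeddings$vectors[t, ], vf), numeric(1))
  sim_last <- vapply(tokens, function(t)
    cosine_similarity(embeddings$vectors[t, ], vl), numeric(1))
  delta <- sim_last - sim_first
  out <- data.frame(token_id = tokens,
                    chapter = if (!is.null(chapter_map))
                      unname(chapter_map[tokens]) else NA_character_,
                    sim_first = sim_first, sim_last = sim_last,
                    delta = delta,
                    direction = ifelse(delta >= 0, "more similar",
                                       "less similar"),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$delta, out$token_id), ]
  rownames(out) <- NULL
  out
}

#' Aggregate similarity deltas by chapter
#'
#' Per chapter: unweighted arithmetic mean of the member tokens' deltas,
#' member count and a direction label by sign; sorted by mean delta
#' (descending).
#'
#' @param deltas the [similarity_change()] output.
#' @param chapter_map named token-to-chapter vector; must cover every
#'   token in `deltas` (unless the deltas already carry chapters).
#' @return data.frame with columns chapter, delta, n_tokens, direction.
#' @export
aggregate_by_chapter <- function(deltas, chapter_map = NULL) {
  ch <- if (!is.null(chapter_map)) {
    unmapped <- setdiff(deltas$token_id, names(chapter_map))
    assert(length(unmapped) == 0, "tokens without chapter: ",
           paste(utils::head(unmapped, 5), collapse = ", "))
    unname(chapter_map[deltas$token_id])
  } else {
    assert(!all(is.na(deltas$chapter)), "no chapter information")
    deltas$chapter
  }
  agg <- stats::aggregate(deltas$delta, by = list(chapter = ch),
                          FUN = mean)
  cnt <- stats::aggregate(deltas$delta, by = list(chapter = ch),
                          FUN = length)
  out <- data.frame(chapter = agg$chapter, delta = agg$x,
                    n_tokens = cnt$x,
                    direction = ifelse(agg$x >= 0, "more similar",
                                       "less similar"),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$delta, out$chapter), ]
  rownames(out) <- NULL
  out
}

#' Export an embedding table in word2vec text format
#'
#' Header line "count dim", then one line per token: the token followed by
#' its coordinates, space-separated.
#'
#' @param embeddings an `embedding_table`.
#' @param path output path.
#' @export
write_embeddings <- function(embeddings, path) {
  stopifnot(inherits(embeddings, "embedding_table"))
  con <- file(path, "w")
  on.exit(close(con))
  m <- embeddings$vectors
  writeLines(sprintf("%d %d", nrow(m), ncol(m)), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(rownames(m)[i],
                     paste(formatC(m[i, ], format = "g", digits = 8),
                           collapse = " ")), con)
  }
  invisible(path)
}
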