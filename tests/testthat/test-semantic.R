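# Stage-3: corpus construction, discretization, patient graph, skip-gram
# embeddings, similarity deltas, chapter aggregation, TF-IDF baseline.

test_that("sequence corpus appends per-chunk outcome tokens", {
  ds <- tiny_high_dataset()
  corpus <- build_sequence_corpus(ds)
  expect_length(corpus$sequences, 3L)
  expect_equal(corpus$sequences$p1, c("dx_a", "dx_b", "deceased@A"))
  expect_equal(corpus$sequences$p2, c("dx_a", "discharged@A"))
  expect_equal(corpus$sequences$p3, c("dx_b", "dx_c", "dx_a",
                                      "deceased@B"))
  # distinct outcome tokens per chunk, both categories tokenized
  expect_setequal(corpus$outcome_token_map$token,
                  c("deceased@A", "discharged@A", "deceased@B"))
  # survivor tokens can be dropped by flag
  corpus2 <- build_sequence_corpus(ds, drop_categories = "discharged")
  expect_equal(corpus2$sequences$p2, "dx_a")
  # zero-event patients become outcome-only sequences, with a warning
  pats <- ds$patients
  ev <- ds$events[ds$events$patient_id != "p2", ]
  ds3 <- chunked_dataset(pats, "high", events = ev)
  expect_warning(corpus3 <- build_sequence_corpus(ds3), "zero events")
  expect_equal(corpus3$sequences$p2, "discharged@A")
})

test_that("equal-width discretization follows the stated conventions", {
  patients <- data.frame(patient_id = sprintf("p%02d", 1:11), chunk = "A",
                         outcome = "discharged", stringsAsFactors = FALSE)
  features <- data.frame(patient_id = patients$patient_id, v = 0:10)
  ds <- chunked_dataset(patients, "low", features = features)
  tok <- discretize_continuous(ds, n_bins = 2)
  bins <- tok$events$token[match(patients$patient_id,
                                 tok$events$patient_id)]
  v <- features$v
  expect_true(all(bins[v < 5] == "v=bin0"))
  # interior edge value 5 goes to the upper bin; max value closes top bin
  expect_true(all(bins[v >= 5] == "v=bin1"))
  expect_equal(bins[v == 10], "v=bin1")
  # roughly uniform occupancy for a uniform sample
  withr::with_seed(2, {
    n <- 4000
    pats <- data.frame(patient_id = sprintf("q%04d", 1:n), chunk = "A",
                       outcome = "discharged", stringsAsFactors = FALSE)
    feats <- data.frame(patient_id = pats$patient_id, u = runif(n))
    tok4 <- discretize_continuous(chunked_dataset(pats, "low",
                                                  features = feats),
                                  n_bins = 4)
    occ <- table(tok4$events$token) / n
    expect_true(all(abs(occ - 0.25) < 0.03))
  })
  # constant feature: single bin with warning
  feats_const <- data.frame(patient_id = patients$patient_id, w = 1)
  expect_warning(
    discretize_continuous(chunked_dataset(patients, "low",
                                          features = feats_const)),
    "constant")
})

test_that("patient graph is bipartite with the documented structure", {
  patients <- data.frame(patient_id = "p1", chunk = "C1",
                         outcome = "deceased", stringsAsFactors = FALSE)
  events <- data.frame(patient_id = "p1", order = 1:3,
                       token = c("age=bin1", "sex=male", "crp=bin0"),
                       stringsAsFactors = FALSE)
  ds <- chunked_dataset(patients, "low",
                        features = data.frame(patient_id = "p1", age = 1))
  ds$events <- events
  g <- build_patient_graph(ds)
  # 1 patient + 3 attribute tokens + 1 outcome token; 3 + 1 edges
  expect_equal(igraph::vcount(g), 5L)
  expect_equal(igraph::ecount(g), 4L)
  expect_true(igraph::is_bipartite(g))
  # shared token gets degree 2
  patients2 <- data.frame(patient_id = c("p1", "p2"), chunk = "C1",
                          outcome = "deceased", stringsAsFactors = FALSE)
  ds2 <- chunked_dataset(patients2, "low",
                         features = data.frame(patient_id = c("p1", "p2"),
                                               age = 1:2))
  ds2$events <- data.frame(patient_id = c("p1", "p2"), order = 1,
                           token = "sex=male", stringsAsFactors = FALSE)
  g2 <- build_patient_graph(ds2)
  expect_equal(unname(igraph::degree(g2, "sex=male")), 2)
})

test_that("skip-gram training covers the vocabulary deterministically", {
  ds <- generate_high_granularity(quick_config(seed = 20))
  corpus <- build_sequence_corpus(ds)
  emb <- train_sequence_embeddings(corpus, dim = 16, epochs = 3, seed = 4)
  vocab <- unique(unlist(corpus$sequences))
  expect_setequal(rownames(emb$vectors), vocab)
  expect_equal(ncol(emb$vectors), 16L)
  emb2 <- train_sequence_embeddings(corpus, dim = 16, epochs = 3,
                                    seed = 4)
  expect_identical(emb$vectors, emb2$vectors)
  emb3 <- train_sequence_embeddings(corpus, dim = 16, epochs = 3,
                                    seed = 5)
  expect_false(identical(emb$vectors, emb3$vectors))
  expect_error(train_sequence_embeddings(corpus, min_count = 1e6),
               "min_count")
})

test_that("co-occurrence structure is recovered by the embeddings", {
  # token x always precedes the outcome token, z never co-occurs with it;
  # 10 seeds here (module example: 95/100)
  hits <- vapply(1:10, function(s) {
    withr::with_seed(s, {
      seqs <- lapply(1:300, function(i) {
        filler <- sample(paste0("f", 1:20), 4, replace = TRUE)
        if (i %% 2 == 0) c(filler[1:2], "x", "death@C") else
          c(filler, "z")
      })
    })
    emb <- train_sequence_embeddings(seqs, dim = 32, epochs = 10,
                                     seed = s)
    v <- emb$vectors
    cs <- function(a, b) sum(v[a, ] * v[b, ]) /
      sqrt(sum(v[a, ]^2) * sum(v[b, ]^2))
    cs("x", "death@C") > cs("z", "death@C")
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("graph embeddings respect structural equivalence", {
  # two attribute tokens attached to identical patient sets embed closer
  # than tokens with disjoint patient sets; 5 seeds
  hits <- vapply(1:5, function(s) {
    n <- 60
    patients <- data.frame(patient_id = sprintf("p%02d", 1:n),
                           chunk = "C1", outcome = "discharged",
                           stringsAsFactors = FALSE)
    half <- patients$patient_id[1:(n / 2)]
    other <- patients$patient_id[(n / 2 + 1):n]
    ev <- rbind(
      data.frame(patient_id = half, order = 1, token = "twin_a"),
      data.frame(patient_id = half, order = 2, token = "twin_b"),
      data.frame(patient_id = other, order = 1, token = "far_c"))
    ds <- chunked_dataset(patients, "low",
                          features = data.frame(patient_id =
                                                  patients$patient_id,
                                                age = 1))
    ds$events <- ev
    g <- build_patient_graph(ds)
    emb <- train_graph_embeddings(g, dim = 16, walk_length = 20,
                                  walks_per_node = 5, epochs = 3,
                                  seed = s)
    v <- emb$vectors
    cs <- function(a, b) sum(v[a, ] * v[b, ]) /
      sqrt(sum(v[a, ]^2) * sum(v[b, ]^2))
    cs("twin_a", "twin_b") > cs("twin_a", "far_c")
  }, logical(1))
  expect_gte(sum(hits), 4)
})

test_that("graph walks are seeded and cover all non-isolated nodes", {
  ds <- discretize_continuous(tiny_low_dataset(), n_bins = 3)
  g <- build_patient_graph(ds)
  e1 <- train_graph_embeddings(g, dim = 8, walk_length = 10,
                               walks_per_node = 2, epochs = 2, seed = 7)
  e2 <- train_graph_embeddings(g, dim = 8, walk_length = 10,
                               walks_per_node = 2, epochs = 2, seed = 7)
  expect_identical(e1$vectors, e2$vectors)
  expect_setequal(rownames(e1$vectors),
                  igraph::V(g)$name[igraph::degree(g) > 0])
  # isolated nodes are excluded with a warning
  g2 <- igraph::add_vertices(g, 1, name = "lonely", type = TRUE,
                             role = "attribute")
  expect_warning(e3 <- train_graph_embeddings(g2, dim = 8,
                                              walk_length = 10,
                                              walks_per_node = 2,
                                              epochs = 2, seed = 7),
                 "isolated")
  expect_false("lonely" %in% rownames(e3$vectors))
})

test_that("similarity_change honors the documented contracts", {
  ds <- generate_high_granularity(quick_config(seed = 12))
  emb <- train_sequence_embeddings(build_sequence_corpus(ds), dim = 16,
                                   epochs = 3, seed = 1)
  first <- ds$chunks[1]; last <- ds$chunks[length(ds$chunks)]
  d <- similarity_change(emb, "deceased", first, last,
                         chapter_map = ds$chapter_map)
  expect_true(all(d$delta >= -2 & d$delta <= 2))
  expect_true(!is.unsorted(rev(d$delta)))
  expect_equal(d$direction, ifelse(d$delta >= 0, "more similar",
                                   "less similar"))
  # the first-chunk outcome token has self-similarity exactly 1
  d_self <- similarity_change(emb, "deceased", first, last,
                              tokens = outcome_token("deceased", first))
  expect_equal(d_self$sim_first, 1)
  expect_error(similarity_change(emb, "deceased", first, "C99"),
               "C99")
})

test_that("chapter aggregation is a permutation-invariant mean", {
  deltas <- data.frame(
    token_id = c("t1", "t2", "t3"),
    chapter = NA_character_,
    sim_first = 0, sim_last = 0,
    delta = c(0.2, 0.4, -0.3),
    direction = c("more similar", "more similar", "less similar"),
    stringsAsFactors = FALSE)
  map <- c(t1 = "chapA", t2 = "chapA", t3 = "chapB")
  agg <- aggregate_by_chapter(deltas, map)
  expect_equal(agg$delta[agg$chapter == "chapA"], 0.3)
  expect_equal(agg$delta[agg$chapter == "chapB"], -0.3)
  expect_equal(agg$n_tokens[agg$chapter == "chapA"], 2L)
  agg2 <- aggregate_by_chapter(deltas[c(3, 1, 2), ], map)
  expect_equal(agg, agg2)
  # loop-based oracle on random deltas
  withr::with_seed(6, {
    k <- 40
    dl <- data.frame(token_id = sprintf("t%02d", 1:k),
                     chapter = NA, sim_first = 0, sim_last = 0,
                     delta = rnorm(k), direction = "more similar",
                     stringsAsFactors = FALSE)
    mp <- setNames(sample(c("c1", "c2", "c3"), k, TRUE), dl$token_id)
    agg3 <- aggregate_by_chapter(dl, mp)
    for (ch in unique(mp)) {
      s <- 0; n <- 0
      for (i in 1:k) if (mp[[dl$token_id[i]]] == ch) {
        s <- s + dl$delta[i]; n <- n + 1
      }
      expect_equal(agg3$delta[agg3$chapter == ch], s / n)
    }
  })
  expect_error(aggregate_by_chapter(deltas, map[-1]), "without chapter")
})

test_that("TF-IDF has minimal idf for ubiquitous terms", {
  ds <- tiny_high_dataset()
  m <- tfidf_matrix(ds)
  idf <- attr(m, "idf")
  # dx_a occurs in every document -> idf at the variant's minimum (1)
  expect_equal(unname(idf["dx_a"]), 1)
  expect_true(all(idf >= 1))
  # rows are unit L2
  expect_equal(unname(sqrt(rowSums(m^2))), rep(1, 3), tolerance = 1e-9)
})

test_that("spectral baseline recovers separable groups and frequencies", {
  withr::with_seed(44, {
    n <- 80
    patients <- data.frame(patient_id = sprintf("p%03d", 1:n),
                           chunk = rep(c("C1", "C2"), n / 2),
                           outcome = "discharged",
                           stringsAsFactors = FALSE)
    ev <- do.call(rbind, lapply(1:n, function(i) {
      pool <- if (i <= n / 2) paste0("A", 1:10) else paste0("B", 1:10)
      data.frame(patient_id = patients$patient_id[i], order = 1:4,
                 token = sample(pool, 4, TRUE),
                 stringsAsFactors = FALSE)
    }))
    ds <- chunked_dataset(patients, "high", events = ev)
  })
  res <- tfidf_cluster_baseline(ds, k_range = 2:6, seed = 10)
  expect_equal(res$k, 2L)
  truth <- rep(1:2, each = 40)
  expect_equal(adjusted_rand_index(res$clusters, truth), 1)
  # cluster frequencies per chunk sum to 1
  expect_equal(unname(colSums(res$chunk_frequencies)), c(1, 1))
  # top features come from the cluster's own vocabulary
  tf1 <- res$top_features[[res$clusters[["p001"]]]]
  expect_true(all(grepl("^A", tf1)))
  expect_error(tfidf_cluster_baseline(ds, k_range = 1:3), ">= 2")
})

test_that("adjusted Rand index matches known values", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  withr::with_seed(1, {
    a <- sample(1:3, 200, TRUE); b <- sample(1:3, 200, TRUE)
    expect_lt(abs(adjusted_rand_index(a, b)), 0.1)
  })
})

test_that("embedding export round-trips through word2vec text format", {
  v <- matrix(rnorm(6), 2, 3, dimnames = list(c("tok_a", "tok_b"), NULL))
  emb <- cohortshift:::new_embedding_table(v, list(algorithm = "sgns"))
  path <- withr::local_tempfile(fileext = ".txt")
  write_embeddings(emb, path)
  lines <- readLines(path)
  expect_equal(lines[1], "2 3")
  parsed <- read.table(text = lines[-1], row.names = 1)
  expect_equal(as.matrix(parsed), v, tolerance = 1e-6,
               ignore_attr = TRUE)
})
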