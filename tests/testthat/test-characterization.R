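# Stage-2 trajectories: prevalence, correlation, importance, centroid
# drift and ranking.

test_that("outcome prevalence is the per-chunk fraction", {
  withr::with_seed(4, {
    patients <- data.frame(
      patient_id = sprintf("p%02d", 1:20),
      chunk = rep(c("A", "B"), each = 10),
      outcome = c(rep("deceased", 2), rep("discharged", 8),
                  rep("deceased", 5), rep("discharged", 5)),
      stringsAsFactors = FALSE)
    features <- data.frame(patient_id = patients$patient_id,
                           age = rnorm(20, 60, 10))
    ds <- chunked_dataset(patients, "low", features = features)
    tr <- outcome_prevalence_over_time(ds)
    expect_equal(unname(tr$values[1, ]), c(0.2, 0.5))
    expect_equal(unname(tr$denominators), c(10, 10))
    expect_error(outcome_prevalence_over_time(ds, "cured"), "unknown")
  })
})

test_that("correlation matches the hand-computed point-biserial toy", {
  patients <- data.frame(patient_id = c("a", "b", "c", "d"), chunk = "A",
                         outcome = c("discharged", "discharged",
                                     "deceased", "deceased"),
                         stringsAsFactors = FALSE)
  features <- data.frame(patient_id = patients$patient_id,
                         x = c(1, 2, 3, 4))
  # needs >= 2 chunks? correlation_over_time works per chunk; single chunk ok
  ds <- chunked_dataset(patients, "low", features = features)
  tr <- correlation_over_time(ds, features = "x")
  # r = 2 / sqrt(5) = 0.8944 (hand evaluation)
  expect_equal(unname(tr$values["x", "A"]), 2 / sqrt(5), tolerance = 1e-6)
  # feature equal to the outcome indicator: r = 1
  features$y <- as.numeric(patients$outcome == "deceased")
  ds2 <- chunked_dataset(patients, "low", features = features)
  tr2 <- correlation_over_time(ds2, features = "y")
  expect_equal(unname(tr2$values["y", "A"]), 1)
  # constant feature is missing, not zero
  features$z <- 5
  ds3 <- chunked_dataset(patients, "low", features = features)
  tr3 <- correlation_over_time(ds3, features = "z")
  expect_true(is.na(tr3$values["z", "A"]))
  expect_error(correlation_over_time(ds, features = "nope"), "unknown")
})

test_that("spearman correlation is rank-based", {
  withr::with_seed(8, {
    n <- 60
    patients <- data.frame(patient_id = sprintf("p%02d", 1:n),
                           chunk = "A",
                           outcome = sample(c("deceased", "discharged"),
                                            n, TRUE),
                           stringsAsFactors = FALSE)
    x <- rlnorm(n)
    features <- data.frame(patient_id = patients$patient_id, x = x)
    ds <- chunked_dataset(patients, "low", features = features)
    sp <- correlation_over_time(ds, features = "x", method = "spearman")
    y <- as.numeric(patients$outcome == "deceased")
    expect_equal(unname(sp$values["x", "A"]),
                 stats::cor(rank(x), y, method = "pearson"),
                 tolerance = 1e-9)
  })
})

test_that("feature importance recovers a dominant feature and normalizes", {
  withr::with_seed(15, {
    n <- 500
    patients <- data.frame(patient_id = sprintf("p%03d", 1:n),
                           chunk = rep(c("A", "B"), each = n / 2),
                           outcome = sample(c("deceased", "discharged"),
                                            n, TRUE),
                           stringsAsFactors = FALSE)
    y <- as.numeric(patients$outcome == "deceased")
    features <- data.frame(patient_id = patients$patient_id,
                           signal = y + rnorm(n, 0, 0.1),
                           noise1 = rnorm(n), noise2 = rnorm(n),
                           noise3 = rnorm(n))
    ds <- chunked_dataset(patients, "low", features = features)
    tr <- feature_importance_over_time(ds, seed = 2)
    expect_equal(unname(colSums(tr$values)), c(1, 1), tolerance = 1e-9)
    expect_true(all(tr$values >= 0))
    for (ch in c("A", "B")) {
      expect_equal(names(which.max(tr$values[, ch])), "signal")
    }
    tr2 <- feature_importance_over_time(ds, seed = 2)
    expect_identical(tr$values, tr2$values)
    # permutation importance agrees on the dominant feature
    trp <- feature_importance_over_time(ds, seed = 2,
                                        importance = "permutation")
    expect_equal(names(which.max(trp$values[, "A"])), "signal")
  })
})

test_that("single-class chunks are skipped with a warning", {
  withr::with_seed(3, {
    patients <- data.frame(patient_id = sprintf("p%02d", 1:40),
                           chunk = rep(c("A", "B"), each = 20),
                           outcome = c(rep("discharged", 20),
                                       sample(c("deceased", "discharged"),
                                              20, TRUE)),
                           stringsAsFactors = FALSE)
    features <- data.frame(patient_id = patients$patient_id,
                           x = rnorm(40), y = rnorm(40))
    ds <- chunked_dataset(patients, "low", features = features)
    expect_warning(tr <- feature_importance_over_time(ds, seed = 1),
                   "single-class")
    expect_true(all(is.na(tr$values[, "A"])))
    expect_false(anyNA(tr$values[, "B"]))
  })
})

test_that("class centroid drift is 0 at reference and bounded", {
  ds <- generate_high_granularity(quick_config(seed = 6))
  tr <- class_centroid_drift(ds)
  expect_setequal(tr$entity, c("deceased", "discharged", "overall"))
  expect_equal(unname(tr$values[, ds$reference_chunk]), rep(0, 3))
  expect_true(all(tr$values >= 0 & tr$values <= 2, na.rm = TRUE))
})

test_that("orthogonal vocabularies give centroid drift 1 for all groups", {
  patients <- data.frame(patient_id = sprintf("p%d", 1:8),
                         chunk = rep(c("A", "B"), each = 4),
                         outcome = rep(c("deceased", "discharged"), 4),
                         stringsAsFactors = FALSE)
  ev <- data.frame(patient_id = patients$patient_id, order = 1,
                   token = c(rep("t1", 4), rep("u1", 4)),
                   stringsAsFactors = FALSE)
  ds <- chunked_dataset(patients, "high", events = ev)
  tr <- class_centroid_drift(ds)
  expect_equal(unname(tr$values[, "B"]), rep(1, 3))
})

test_that("top_k_trajectories ranks by absolute value with lexical ties", {
  tt <- cohortshift:::new_trajectory_table(
    entity = c("b_feat", "a_feat", "c_feat"),
    chunk_labels = c("C1", "C2"),
    values = matrix(c(0.5, 0.5, -0.5, -0.5, 0.1, 0.1), nrow = 3,
                    byrow = TRUE),
    statistic = "pearson")
  # a_feat and b_feat tie at |0.5|: lexicographic order breaks the tie
  expect_equal(top_k_trajectories(tt, 2), c("a_feat", "b_feat"))
  expect_equal(top_k_trajectories(tt, 1, ranking_chunk = "C2"), "a_feat")
  # full ordering agrees with a naive sort oracle
  score <- rowMeans(abs(tt$values))
  oracle <- tt$entity[order(-score, tt$entity)]
  expect_equal(top_k_trajectories(tt, 3), oracle)
  expect_error(top_k_trajectories(tt, 4), "exceeds")
})
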