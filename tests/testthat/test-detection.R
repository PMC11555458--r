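# Drift metrics. DERIVED expectations are frozen from independent oracles
# computed inline (direct-summation JSD, loop-based means, explicit SVD).

test_that("Jensen-Shannon divergence matches hand-evaluated cases", {
  expect_equal(jensen_shannon_divergence(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(jensen_shannon_divergence(c(1, 0), c(0, 1)), 1)
  # (1,0) vs (0.5,0.5): M=(0.75,0.25); 0.5*log2(1/0.75) + 0.25*log2(...)
  expect_equal(jensen_shannon_divergence(c(1, 0), c(0.5, 0.5)), 0.3113,
               tolerance = 1e-4)
  # natural-log variant is ln(2) times smaller
  expect_equal(jensen_shannon_divergence(c(1, 0), c(0, 1), base = exp(1)),
               log(2))
  expect_error(jensen_shannon_divergence(c(0.6, 0.6), c(0.5, 0.5)),
               "normalized")
  p <- freq_dist(c(a = 1, b = 1), epsilon = 0)
  q <- freq_dist(c(x = 1, y = 1), epsilon = 0)
  expect_error(jensen_shannon_divergence(p, q), "vocabular")
})

test_that("JSD agrees with a direct-summation oracle on random pairs", {
  # independent oracle: literal term-by-term evaluation of the two KL sums
  jsd_oracle <- function(p, q) {
    m <- (p + q) / 2
    tot <- 0
    for (i in seq_along(p)) {
      if (p[i] > 0) tot <- tot + 0.5 * p[i] * log2(p[i] / m[i])
      if (q[i] > 0) tot <- tot + 0.5 * q[i] * log2(q[i] / m[i])
    }
    tot
  }
  withr::with_seed(99, {
    for (i in 1:300) {
      k <- sample(2:30, 1)
      p <- rgamma(k, 1); p <- p / sum(p)
      q <- rgamma(k, 1); q <- q / sum(q)
      v <- jensen_shannon_divergence(p, q)
      expect_equal(v, jsd_oracle(p, q), tolerance = 1e-10)
      expect_equal(v, jensen_shannon_divergence(q, p), tolerance = 1e-12)
      expect_gte(v, 0)
      expect_lte(v, 1)
    }
  })
})

test_that("centroid and cosine distance behave as documented", {
  expect_equal(centroid(matrix(c(1, 2, 3), 1)), c(1, 2, 3))
  expect_equal(centroid(list(c(1, 0), c(0, 1))), c(0.5, 0.5))
  # brute-force column means oracle on a random matrix
  withr::with_seed(7, {
    m <- matrix(rnorm(12), 4, 3)
    oracle <- sapply(1:3, function(j) {
      s <- 0
      for (i in 1:4) s <- s + m[i, j]
      s / 4
    })
    expect_equal(unname(centroid(m)), oracle)
  })
  expect_error(centroid(list()), "empty")
  expect_equal(cosine_distance(c(2, 1), c(2, 1)), 0)
  expect_equal(cosine_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(cosine_distance(c(1, 1), c(1, 0)), 1 - 1 / sqrt(2))
  expect_error(cosine_distance(c(0, 0), c(1, 0)), "zero-norm")
})

test_that("normalize_signal rescales to [0, 1] with degenerate handling", {
  expect_equal(normalize_signal(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(normalize_signal(c(3, 3, 3)), c(0, 0, 0))
  withr::with_seed(5, {
    for (i in 1:50) {
      x <- rnorm(sample(2:20, 1))
      n <- normalize_signal(x)
      expect_equal(min(n), 0)
      expect_equal(max(n), if (length(unique(x)) > 1) 1 else 0)
    }
  })
})

test_that("centroid signal is 0 for identical and 1 for disjoint chunks", {
  patients <- data.frame(patient_id = sprintf("p%d", 1:4),
                         chunk = rep(c("A", "B"), each = 2),
                         outcome = "discharged", stringsAsFactors = FALSE)
  events_same <- data.frame(patient_id = rep(patients$patient_id, 2),
                            order = rep(1:2, each = 4),
                            token = rep(c("t1", "t2"), 4),
                            stringsAsFactors = FALSE)
  ds_same <- chunked_dataset(patients, "high", events = events_same)
  expect_equal(centroid_cosine_signal(ds_same)$raw_values, c(0, 0))
  events_disjoint <- data.frame(
    patient_id = patients$patient_id, order = 1,
    token = c("t1", "t2", "u1", "u2"), stringsAsFactors = FALSE)
  ds_dis <- chunked_dataset(patients, "high", events = events_disjoint)
  expect_equal(centroid_cosine_signal(ds_dis)$raw_values, c(0, 1))
})

test_that("PCA signal matches analytic projection residuals", {
  # reference on a 2-D line, k = 1: residual is squared perpendicular
  # distance of the target point
  patients <- data.frame(patient_id = sprintf("p%d", 1:7),
                         chunk = c(rep("A", 6), "B"),
                         outcome = "discharged", stringsAsFactors = FALSE)
  line <- cbind(seq(-2.5, 2.5, 1), seq(-2.5, 2.5, 1))  # centered line y=x
  d_perp <- 1.5
  target <- c(-d_perp / sqrt(2), d_perp / sqrt(2))     # off-line point
  features <- data.frame(patient_id = patients$patient_id,
                         f1 = c(line[, 1], target[1] + mean(line[, 1])),
                         f2 = c(line[, 2], target[2] + mean(line[, 2])))
  ds <- chunked_dataset(patients, "low", features = features)
  sig <- pca_reconstruction_signal(ds, n_components = 1, scale. = FALSE)
  expect_equal(sig$raw_values[[1]], 0, tolerance = 1e-9)
  expect_equal(sig$raw_values[[2]], d_perp^2, tolerance = 1e-9)

  # in-sample residual oracle via explicit SVD on a 6 x 3 matrix
  withr::with_seed(11, {
    m <- matrix(rnorm(18), 6, 3)
    pats <- data.frame(patient_id = sprintf("q%d", 1:6),
                       chunk = "A", outcome = "discharged")
    pats$chunk[6] <- "B"   # need >= 2 chunks; reference is rows 1-5
    feats <- data.frame(patient_id = pats$patient_id, m)
    ds2 <- chunked_dataset(pats, "low", features = feats)
    sig2 <- pca_reconstruction_signal(ds2, n_components = 2,
                                      scale. = FALSE)
    ref <- m[1:5, ]
    refc <- scale(ref, scale = FALSE)
    sv <- svd(refc)
    V <- sv$v[, 1:2]
    resid <- refc - refc %*% V %*% t(V)
    expect_equal(sig2$raw_values[[1]], mean(rowSums(resid^2)),
                 tolerance = 1e-9)
  })
  # rank guard
  expect_error(pca_reconstruction_signal(ds, n_components = 5,
                                         scale. = FALSE),
               "exceeds reference rank")
})

test_that("full-rank PCA reconstructs subspace data exactly", {
  withr::with_seed(21, {
    base <- matrix(rnorm(8), 4, 2)
    coef <- matrix(rnorm(40), 20, 2)
    x <- coef %*% t(base)          # rank-2 data in 4 dims
    pats <- data.frame(patient_id = sprintf("r%02d", 1:20),
                       chunk = rep(c("A", "B"), each = 10),
                       outcome = "discharged")
    feats <- data.frame(patient_id = pats$patient_id, x)
    ds <- chunked_dataset(pats, "low", features = feats)
    sig <- pca_reconstruction_signal(ds, n_components = 2, scale. = FALSE)
    expect_true(all(sig$raw_values < 1e-9))
  })
})

test_that("linear autoencoder attains near-PCA reconstruction", {
  withr::with_seed(31, {
    base <- matrix(rnorm(10), 5, 2)
    x <- matrix(rnorm(60), 30, 2) %*% t(base)  # intrinsic dim 2 in 5 dims
    model <- cohortshift:::ae_train(scale(x, scale = FALSE),
                                    bottleneck = 2,
                                    activation = "linear",
                                    epochs = 1500, lr = 0.02, seed = 2)
    err <- mean((cohortshift:::ae_predict(model, scale(x, scale = FALSE)) -
                   scale(x, scale = FALSE))^2)
    expect_lt(err, 1e-3)
  })
})

test_that("autoencoder signal is seeded-deterministic", {
  ds <- generate_high_granularity(quick_config(seed = 8))
  s1 <- autoencoder_reconstruction_signal(ds, epochs = 30, seed = 5)
  s2 <- autoencoder_reconstruction_signal(ds, epochs = 30, seed = 5)
  expect_identical(s1$raw_values, s2$raw_values)
  s3 <- autoencoder_reconstruction_signal(ds, epochs = 30, seed = 6)
  expect_false(identical(s1$raw_values, s3$raw_values))
})

test_that("classifier signal separates a planted token and not a null", {
  # target chunk has a token absent from reference in every patient
  withr::with_seed(13, {
    n <- 60
    patients <- data.frame(patient_id = sprintf("p%02d", 1:n),
                           chunk = rep(c("A", "B"), each = n / 2),
                           outcome = "discharged", stringsAsFactors = FALSE)
    ev <- data.frame(
      patient_id = rep(patients$patient_id, each = 3),
      order = rep(1:3, n),
      token = c(replicate(n / 2, sample(paste0("t", 1:6), 3)),
                replicate(n / 2, c("marker",
                                   sample(paste0("t", 1:6), 2)))),
      stringsAsFactors = FALSE)
    ds <- chunked_dataset(patients, "high", events = ev)
    sig <- classifier_error_signal(ds, seed = 3)
    expect_gte(sig$raw_values[[2]], 0.95)
    # reference-vs-itself entry is near chance
    expect_lt(abs(sig$raw_values[[1]] - 0.5), 0.25)
  })
})

test_that("detect_drift applies the k-SD rule with fallback", {
  # hand computation: window (1, 1, 2) -> mean 1.333, sd 0.577,
  # threshold at k=2 is 2.488 -> the value 10 flags
  flags <- detect_drift(c(1, 1, 2, 10), k_sd = 2, reference_window = 3)
  expect_equal(which(flags), 4L)
  # zero-variance window falls back with a warning and still flags
  expect_warning(flags2 <- detect_drift(c(1, 1, 1, 10), k_sd = 2,
                                        reference_window = 3),
                 "zero-variance")
  expect_equal(which(flags2), 4L)
  # flat signal: no flags
  expect_warning(flags3 <- detect_drift(rep(2, 6), k_sd = 2,
                                        reference_window = 3))
  expect_equal(sum(flags3), 0L)
  # flagged values are excluded from the expanding baseline
  flags4 <- detect_drift(c(1, 1.1, 0.9, 10, 1.05, 12),
                         k_sd = 3, reference_window = 3)
  expect_equal(which(flags4), c(4L, 6L))
  expect_error(detect_drift(c(1, 2), reference_window = 5), "at least")
})

test_that("signal series cover all chunks and normalize to [0, 1]", {
  ds <- generate_high_granularity(quick_config(seed = 3))
  for (sig in list(jsd_signal(ds), centroid_cosine_signal(ds),
                   pca_reconstruction_signal(ds))) {
    expect_equal(sig$chunk_labels, ds$chunks)
    expect_equal(length(sig$raw_values), length(ds$chunks))
    expect_true(all(sig$normalized_values >= 0 &
                      sig$normalized_values <= 1))
    expect_equal(sig$raw_values[[1]],
                 if (sig$metric_name %in% c("jsd", "centroid")) 0 else
                   sig$raw_values[[1]])
  }
  # consecutive-chunk comparison mode exists and differs
  sref <- jsd_signal(ds, comparison = "reference")
  scon <- jsd_signal(ds, comparison = "consecutive")
  expect_false(identical(sref$raw_values[3:4], scon$raw_values[3:4]))
})
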