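## Synthetic cohort generator with injectable temporal drifts.
##
## The generator is the package's stand-in for credentialed clinical data:
## it emulates (a) an event-level cohort with a Zipf-distributed token
## vocabulary grouped into chapters and a binary outcome driven by a
## logistic model on designated risk tokens, and (b) a snapshot cohort with
## mixed numeric/categorical attributes, admission dates and a logistic
## outcome. Four drift trajectory types (sudden, incremental, gradual,
## reoccurring) can be injected on four targets.

#' Define a drift scenario
#'
#' @param drift_type trajectory over time: `"sudden"` (step at onset),
#'   `"incremental"` (linear parameter ramp from onset to the last chunk),
#'   `"gradual"` (per-patient mixture of old/new regimes whose new-regime
#'   probability ramps from onset), `"reoccurring"` (periodic alternation
#'   of old/new regime from onset).
#' @param target what the drift acts on: `"token_frequency"` (event token
#'   distribution), `"outcome_prevalence"`, `"token_outcome_association"`
#'   (logistic coefficient of a risk token / feature), `"numeric_outlier"`
#'   (injected extreme values in a numeric feature).
#' @param onset_chunk 1-based chunk index at which the drift starts.
#' @param magnitude effect size, target-specific: multiplicative factor on
#'   the affected tokens' probability mass (token_frequency), on the
#'   prevalence (outcome_prevalence) or on the logistic coefficient
#'   (token_outcome_association; 0 switches the association off), or the
#'   number of feature standard deviations for injected outliers.
#' @param period alternation period in chunks (reoccurring only, >= 2).
#' @param tokens affected event tokens (token_frequency /
#'   token_outcome_association in high mode); default chosen by the
#'   generator (ranks 6-10 of the baseline distribution for frequency
#'   drifts, the first risk token for association drifts).
#' @param feature affected feature name (low mode).
#' @param outcome_class restrict a token_frequency drift to patients with
#'   this outcome (e.g. `"deceased"`): only that class's event
#'   distribution shifts. See the methods vignette for the mechanism.
#' @return A `drift_scenario` object.
#' @export
drift_scenario <- function(drift_type = c("sudden", "incremental",
                                          "gradual", "reoccurring"),
                           target = c("token_frequency",
                                      "outcome_prevalence",
                                      "token_outcome_association",
                                      "numeric_outlier"),
                           onset_chunk, magnitude, period = NULL,
                           tokens = NULL, feature = NULL,
                           outcome_class = NULL) {
  drift_type <- match.arg(drift_type)
  target <- match.arg(target)
  assert(is.numeric(onset_chunk) && onset_chunk >= 1,
         "onset_chunk must be a positive chunk index")
  assert(is.numeric(magnitude) && magnitude >= 0, "magnitude must be >= 0")
  if (drift_type == "reoccurring") {
    assert(!is.null(period) && period >= 2,
           "reoccurring drift needs period >= 2")
  }
  structure(list(drift_type = drift_type, target = target,
                 onset_chunk = as.integer(onset_chunk),
                 magnitude = magnitude, period = period,
                 tokens = tokens, feature = feature,
                 outcome_class = outcome_class),
            class = "drift_scenario")
}

#' Configure a synthetic cohort
#'
#' Defaults describe a mid-sized monitoring problem: 5 quarterly chunks of
#' 500 patients, a 100-token vocabulary in 10 chapters with Zipf(1.1)
#' baseline usage, ~10 events per patient and 20% baseline outcome
#' prevalence (the death rate reported for hospitalized COVID-19 cohorts).
#'
#' @param n_patients_per_chunk patients per temporal chunk.
#' @param n_chunks number of temporal chunks.
#' @param vocabulary_size number of distinct event tokens (high mode).
#' @param n_chapters number of chapter groups the vocabulary is split into.
#' @param zipf_exponent exponent of the Zipf baseline token distribution.
#' @param baseline_outcome_prevalence probability of the positive outcome
#'   (`"deceased"`) in the baseline regime.
#' @param events_per_patient list(mean, min): event count per patient is
#'   `min + Poisson(mean - min)`.
#' @param risk_tokens tokens whose presence raises the death odds (high
#'   mode); default: tokens ranked 11-13 of the baseline distribution,
#'   whose per-patient prevalence (~15% at the default event count)
#'   matches the 5-30% range of common comorbidities.
#' @param risk_beta logistic coefficient shared by the risk tokens.
#' @param outlier_fraction fraction of patients receiving an injected
#'   outlier under an active numeric_outlier scenario. The default 0.002
#'   emulates the "small number" of entry-error outliers seen in registry
#'   data (a handful of rows per thousand patients); pair it with a
#'   magnitude of ~100 SDs (orders of magnitude above typical values,
#'   e.g. a heart rate recorded as 1600).
#' @param scenarios list of [drift_scenario()] objects.
#' @param seed integer RNG seed; identical seed, identical cohort.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n_patients_per_chunk = 500L, n_chunks = 5L,
                          vocabulary_size = 100L, n_chapters = 10L,
                          zipf_exponent = 1.1,
                          baseline_outcome_prevalence = 0.2,
                          events_per_patient = list(mean = 10, min = 2),
                          risk_tokens = NULL, risk_beta = 1.0,
                          outlier_fraction = 0.002,
                          scenarios = list(), seed = 1L) {
  assert(n_patients_per_chunk >= 1 && n_chunks >= 1, "need patients and chunks")
  assert(vocabulary_size >= n_chapters,
         "vocabulary_size must be >= n_chapters")
  assert(baseline_outcome_prevalence > 0 && baseline_outcome_prevalence < 1,
         "baseline prevalence must be in (0,1)")
  if (inherits(scenarios, "drift_scenario")) scenarios <- list(scenarios)
  for (sc in scenarios) {
    assert(inherits(sc, "drift_scenario"), "scenarios must be drift_scenario")
    assert(sc$onset_chunk <= n_chunks,
           "impossible scenario: onset_chunk ", sc$onset_chunk,
           " beyond n_chunks ", n_chunks)
  }
  structure(list(n_patients_per_chunk = as.integer(n_patients_per_chunk),
                 n_chunks = as.integer(n_chunks),
                 vocabulary_size = as.integer(vocabulary_size),
                 n_chapters = as.integer(n_chapters),
                 zipf_exponent = zipf_exponent,
                 baseline_outcome_prevalence = baseline_outcome_prevalence,
                 events_per_patient = events_per_patient,
                 risk_tokens = risk_tokens, risk_beta = risk_beta,
                 outlier_fraction = outlier_fraction,
                 scenarios = scenarios, seed = as.integer(seed)),
            class = "cohort_config")
}

## Ramp weight for incremental/gradual drifts: 0 just before onset, 1 at
## the last chunk, linear in between. At onset it already moves.
ramp_weight <- function(onset, chunk_idx, n_chunks) {
  if (chunk_idx < onset) return(0)
  span <- n_chunks - onset + 1L
  (chunk_idx - onset + 1L) / span
}

scenario_weights <- function(sc, n_chunks) {
  vapply(seq_len(n_chunks), function(i) {
    if (i < sc$onset_chunk) return(0)
    switch(sc$drift_type,
      sudden = 1,
      incremental = ramp_weight(sc$onset_chunk, i, n_chunks),
      gradual = ramp_weight(sc$onset_chunk, i, n_chunks),
      reoccurring = {
        half <- max(1L, floor(sc$period / 2))
        as.numeric(((i - sc$onset_chunk) %% sc$period) < half)
      })
  }, numeric(1))
}

## Apply token_frequency scenarios to the baseline probability vector for
## one chunk. `w` already encodes the trajectory. Gradual drifts are
## handled at the patient level by the caller (regime mixing), so here they
## contribute their full "new regime" distribution.
drifted_token_probs <- function(base_probs, scenarios, weights, full_regime) {
  p <- base_probs
  for (k in seq_along(scenarios)) {
    sc <- scenarios[[k]]
    ## class-conditional scenarios are applied by the caller, post outcome
    if (sc$target != "token_frequency" || !is.null(sc$outcome_class)) next
    w <- if (full_regime) (weights[k] > 0) * 1 else weights[k]
    if (w <= 0) next
    factor <- 1 + (sc$magnitude - 1) * w
    idx <- match(sc$tokens, names(p))
    p[idx] <- p[idx] * factor
    p <- p / sum(p)
  }
  p
}

## Calibrate the logistic intercept so that mean plogis(a + lp) == target.
calibrate_intercept <- function(lp, target) {
  f <- function(a) mean(stats::plogis(a + lp)) - target
  stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
}

#' Generate a high-granularity (event-level) synthetic cohort
#'
#' Per chunk, each patient draws an ordered sequence of event tokens from a
#' chunk-specific Zipf-based distribution modified by the configured
#' scenarios; the binary outcome is drawn from a logistic model on risk
#' token indicators whose intercept is calibrated per chunk to the
#' (possibly drifting) target prevalence. Identical seed, identical cohort.
#'
#' @param config a [cohort_config()].
#' @return A high-granularity `chunked_dataset` whose `$truth` field records
#'   the realized drift schedule (per-chunk token distributions, scenario
#'   weights, prevalences and coefficients) for recovery experiments.
#' @export
generate_high_granularity <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    V <- config$vocabulary_size
    vocab <- sprintf("icd_%03d", seq_len(V))
    chapters <- sprintf("chap_%02d", rep(seq_len(config$n_chapters),
                                         length.out = V))
    chapter_map <- setNames(chapters, vocab)
    base <- seq_len(V)^(-config$zipf_exponent)
    base <- setNames(base / sum(base), vocab)
    risk_tokens <- config$risk_tokens %||% vocab[11:13]
    scen <- lapply(config$scenarios, function(sc) {
      if (sc$target == "token_frequency" && is.null(sc$tokens)) {
        sc$tokens <- vocab[6:10]
      }
      if (sc$target == "token_outcome_association" && is.null(sc$tokens)) {
        sc$tokens <- risk_tokens[1]
      }
      sc
    })
    n_chunks <- config$n_chunks
    chunk_labels <- sprintf("C%02d", seq_len(n_chunks))
    npc <- config$n_patients_per_chunk
    wmat <- if (length(scen)) {
      vapply(scen, scenario_weights, numeric(n_chunks),
             n_chunks = n_chunks)
    } else {
      matrix(0, n_chunks, 0)
    }
    ev_mean <- config$events_per_patient$mean %||% 10
    ev_min <- config$events_per_patient$min %||% 2

    all_pat <- vector("list", n_chunks)
    all_ev <- vector("list", n_chunks)
    truth_chunks <- vector("list", n_chunks)
    for (ci in seq_len(n_chunks)) {
      w <- if (length(scen)) wmat[ci, ] else numeric(0)
      ## event-distribution regimes for this chunk
      grad_idx <- which(vapply(scen, function(s)
        s$target == "token_frequency" && s$drift_type == "gradual" &&
          is.null(s$outcome_class), logical(1)))
      p_param <- drifted_token_probs(base, scen_drop(scen, grad_idx),
                                     w_drop(w, grad_idx), FALSE)
      p_new <- drifted_token_probs(base, scen, pmin(w, 1), TRUE)
      mix_w <- if (length(grad_idx)) max(w[grad_idx]) else 0

      ids <- sprintf("p%s_%04d", chunk_labels[ci], seq_len(npc))
      n_ev <- ev_min + stats::rpois(npc, max(ev_mean - ev_min, 0))
      regime_new <- stats::runif(npc) < mix_w
      events <- vector("list", npc)
      for (i in seq_len(npc)) {
        p_i <- if (regime_new[i]) p_new else p_param
        events[[i]] <- sample(vocab, n_ev[i], replace = TRUE, prob = p_i)
      }
      ## logistic outcome on risk-token indicators. An association
      ## scenario shifts a token's coefficient by w*(magnitude-1)*risk_beta
      ## from its baseline (risk_beta for configured risk tokens, 0 for an
      ## emergent factor): magnitude 0 decouples a risk token, magnitude 4
      ## turns a neutral token into a strong risk marker.
      assoc_tokens <- unlist(lapply(scen, function(s)
        if (s$target == "token_outcome_association") s$tokens))
      all_risk <- union(risk_tokens, assoc_tokens)
      beta <- setNames(ifelse(all_risk %in% risk_tokens,
                              config$risk_beta, 0), all_risk)
      for (k in seq_along(scen)) {
        sc <- scen[[k]]
        if (sc$target != "token_outcome_association") next
        beta[sc$tokens] <- beta[sc$tokens] +
          w[k] * (sc$magnitude - 1) * config$risk_beta
      }
      ind <- vapply(names(beta), function(t)
        vapply(events, function(e) as.numeric(t %in% e), numeric(1)),
        numeric(npc))
      if (is.null(dim(ind))) ind <- matrix(ind, nrow = npc)
      lp <- as.numeric(ind %*% beta)
      prev <- config$baseline_outcome_prevalence
      for (k in seq_along(scen)) {
        sc <- scen[[k]]
        if (sc$target == "outcome_prevalence" && w[k] > 0) {
          prev <- prev * ((1 - w[k]) + w[k] * sc$magnitude)
        }
      }
      prev <- min(max(prev, 1e-4), 1 - 1e-4)
      a <- calibrate_intercept(lp, prev)
      dead <- stats::runif(npc) < stats::plogis(a + lp)
      ## class-conditional frequency drift: redraw affected class's events
      ## from the drifted distribution (see vignette)
      for (k in seq_along(scen)) {
        sc <- scen[[k]]
        if (sc$target != "token_frequency" || is.null(sc$outcome_class) ||
            w[k] <= 0) next
        sc_all <- sc; sc_all$outcome_class <- NULL
        p_cls <- drifted_token_probs(base, list(sc_all), w[k], FALSE)
        sel <- if (sc$outcome_class == "deceased") which(dead) else
          which(!dead)
        for (i in sel) {
          events[[i]] <- sample(vocab, length(events[[i]]),
                                replace = TRUE, prob = p_cls)
        }
      }
      all_pat[[ci]] <- data.frame(
        patient_id = ids, chunk = chunk_labels[ci],
        outcome = ifelse(dead, "deceased", "discharged"),
        stringsAsFactors = FALSE)
      all_ev[[ci]] <- data.frame(
        patient_id = rep(ids, lengths(events)),
        order = unlist(lapply(lengths(events), seq_len)),
        token = unlist(events), stringsAsFactors = FALSE)
      truth_chunks[[ci]] <- list(token_probs = p_param, mix_weight = mix_w,
                                 prevalence = prev, beta = beta)
    }
    chunked_dataset(do.call(rbind, all_pat), mode = "high",
                    events = do.call(rbind, all_ev),
                    chunks = chunk_labels, chapter_map = chapter_map,
                    outcome_levels = c("deceased", "discharged"),
                    truth = list(config = config, scenarios = scen,
                                 chunks = truth_chunks,
                                 risk_tokens = risk_tokens))
  })
}

scen_drop <- function(scen, idx) if (length(idx)) scen[-idx] else scen
w_drop <- function(w, idx) if (length(idx)) w[-idx] else w

## Numeric feature families of the snapshot generator: roughly
## admission-physiology-shaped, lognormal where clinically heavy-tailed.
LOW_NUMERIC <- list(
  age        = list(dist = "normal", mean = 60, sd = 16),
  heart_rate = list(dist = "normal", mean = 85, sd = 15),
  resp_rate  = list(dist = "normal", mean = 20, sd = 5),
  sodium     = list(dist = "normal", mean = 138, sd = 4),
  fio2       = list(dist = "normal", mean = 0.35, sd = 0.12),
  crp        = list(dist = "lognormal", meanlog = log(60), sdlog = 0.8))
LOW_CATEG <- list(
  sex = c(male = 0.55, female = 0.45),
  hypertension = c(yes = 0.5, no = 0.5),
  diabetes = c(yes = 0.26, no = 0.74))
## standardized logistic coefficients of the snapshot outcome model
LOW_BETA <- c(age = 0.9, fio2 = 0.7, crp = 0.4, sodium = -0.3,
              `hypertension=yes` = 0.3)

#' Generate a low-granularity (snapshot) synthetic cohort
#'
#' One row per patient: age and vital-sign-like numeric attributes (normal
#' or lognormal), categorical comorbidities, an admission date uniform
#' within the patient's quarterly chunk, and a binary outcome from a
#' logistic model on standardized features (intercept calibrated per chunk
#' to the target prevalence). `token_outcome_association` scenarios on a
#' feature (e.g. age, emulating a vaccination-era decoupling) rescale its
#' coefficient from the onset chunk; `numeric_outlier` scenarios inject
#' values at `magnitude` standard deviations into a fraction of patients.
#'
#' @param config a [cohort_config()].
#' @return A low-granularity `chunked_dataset` with ground truth in `$truth`.
#' @export
generate_low_granularity <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n_chunks <- config$n_chunks
    chunk_labels <- sprintf("C%02d", seq_len(n_chunks))
    npc <- config$n_patients_per_chunk
    scen <- config$scenarios
    wmat <- if (length(scen)) {
      vapply(scen, scenario_weights, numeric(n_chunks), n_chunks = n_chunks)
    } else {
      matrix(0, n_chunks, 0)
    }
    q_starts <- seq(as.Date("2020-01-01"), by = "3 months",
                    length.out = n_chunks + 1L)
    all_pat <- vector("list", n_chunks)
    all_feat <- vector("list", n_chunks)
    truth_chunks <- vector("list", n_chunks)
    for (ci in seq_len(n_chunks)) {
      w <- if (length(scen)) wmat[ci, ] else numeric(0)
      ids <- sprintf("p%s_%04d", chunk_labels[ci], seq_len(npc))
      feat <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
      for (fn in names(LOW_NUMERIC)) {
        d <- LOW_NUMERIC[[fn]]
        feat[[fn]] <- if (d$dist == "normal") {
          stats::rnorm(npc, d$mean, d$sd)
        } else {
          stats::rlnorm(npc, d$meanlog, d$sdlog)
        }
      }
      for (fn in names(LOW_CATEG)) {
        p <- LOW_CATEG[[fn]]
        feat[[fn]] <- sample(names(p), npc, replace = TRUE, prob = p)
      }
      ## outlier injection (before the outcome model: outliers are
      ## measurement artefacts, not risk modifiers)
      n_outliers <- 0L
      for (k in seq_along(scen)) {
        sc <- scen[[k]]
        if (sc$target != "numeric_outlier" || w[k] <= 0 ||
            sc$magnitude <= 0) next
        fn <- sc$feature %||% "heart_rate"
        d <- LOW_NUMERIC[[fn]]
        sdev <- if (d$dist == "normal") d$sd else
          sqrt((exp(d$sdlog^2) - 1) * exp(2 * d$meanlog + d$sdlog^2))
        mu <- if (d$dist == "normal") d$mean else exp(d$meanlog + d$sdlog^2 / 2)
        n_o <- max(1L, round(config$outlier_fraction * npc * w[k]))
        rows <- sample.int(npc, n_o)
        feat[[fn]][rows] <- mu + sc$magnitude * sdev
        n_outliers <- n_outliers + n_o
      }
      ## logistic outcome on standardized features
      beta <- LOW_BETA
      for (k in seq_along(scen)) {
        sc <- scen[[k]]
        if (sc$target != "token_outcome_association" || w[k] <= 0) next
        fn <- sc$feature %||% "age"
        nm <- if (fn %in% names(beta)) fn else paste0(fn, "=yes")
        if (nm %in% names(beta)) {
          beta[nm] <- beta[nm] * ((1 - w[k]) + w[k] * sc$magnitude)
        }
      }
      z <- function(fn) {
        d <- LOW_NUMERIC[[fn]]
        if (d$dist == "normal") {
          (feat[[fn]] - d$mean) / d$sd
        } else {
          (log(feat[[fn]]) - d$meanlog) / d$sdlog
        }
      }
      lp <- beta[["age"]] * z("age") + beta[["fio2"]] * z("fio2") +
        beta[["crp"]] * z("crp") + beta[["sodium"]] * z("sodium") +
        beta[["hypertension=yes"]] * (feat$hypertension == "yes")
      prev <- config$baseline_outcome_prevalence
      for (k in seq_along(scen)) {
        sc <- scen[[k]]
        if (sc$target == "outcome_prevalence" && w[k] > 0) {
          prev <- prev * ((1 - w[k]) + w[k] * sc$magnitude)
        }
      }
      prev <- min(max(prev, 1e-4), 1 - 1e-4)
      a <- calibrate_intercept(lp, prev)
      dead <- stats::runif(npc) < stats::plogis(a + lp)
      span <- as.numeric(q_starts[ci + 1] - q_starts[ci])
      feat$admission_date <- q_starts[ci] +
        floor(stats::runif(npc) * span)
      all_pat[[ci]] <- data.frame(
        patient_id = ids, chunk = chunk_labels[ci],
        outcome = ifelse(dead, "deceased", "discharged"),
        stringsAsFactors = FALSE)
      all_feat[[ci]] <- feat
      truth_chunks[[ci]] <- list(beta = beta, prevalence = prev,
                                 n_outliers = n_outliers)
    }
    chunked_dataset(do.call(rbind, all_pat), mode = "low",
                    features = do.call(rbind, all_feat),
                    chunks = chunk_labels,
                    outcome_levels = c("deceased", "discharged"),
                    truth = list(config = config, chunks = truth_chunks))
  })
}

#' Write the generator's ground-truth drift schedule as JSON
#'
#' Sidecar for recovery experiments: which scenarios were injected, with
#' which per-chunk weights, prevalences and coefficients.
#'
#' @param dataset a generated `chunked_dataset` (with `$truth`).
#' @param path output JSON path.
#' @export
write_truth <- function(dataset, path) {
  stopifnot(inherits(dataset, "chunked_dataset"))
  assert(!is.null(dataset$truth), "dataset carries no ground truth")
  tr <- dataset$truth
  out <- list(
    scenarios = lapply(tr$scenarios %||% tr$config$scenarios, unclass),
    chunks = lapply(tr$chunks, function(ch) {
      ch$token_probs <- NULL   # bulky; recomputable from config
      ch
    }),
    seed = tr$config$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
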