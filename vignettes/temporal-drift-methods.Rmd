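---
title: "Detecting and explaining temporal drifts in patient cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and explaining temporal drifts in patient cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Health care data drift. Vaccination campaigns change who is hospitalized
and who dies; treatment advances decouple a diagnosis from its historical
lethality; coding practices and collection software change what is even
recorded. A model trained on last year's cohort silently degrades, and —
more interestingly for health services research — the drift itself carries
information about what changed in care.

`cohortshift` implements a three-stage workflow for such analyses:

1. **Detection** — is the cohort's distribution changing across temporal
   chunks?
2. **Initial characterization** — *what* changed, globally: the outcome
   rate `P(y)`, the feature distributions `P(x)`, and the
   feature–outcome relationship `P(y|x)`.
3. **Semantic characterization** — *why*, locally: which clinical
   concepts moved closer to or further from the outcome, measured in a
   learned embedding space.

A cohort is a `chunked_dataset`: patients partitioned into ordered
temporal chunks (quarters, year groups, ...), with the first chunk as the
reference unless overridden. Two granularity modes are supported. In
*high* granularity each patient carries an ordered sequence of discrete
event tokens (ICD codes, consumed items); in *low* granularity each
patient is a single snapshot of mixed attributes. The granularity only
changes stage 3's machinery (sequence embeddings vs graph embeddings).

## Stage 1: detection

Five metrics compare each chunk against the reference chunk (a
consecutive-chunk mode is available by flag; the default follows the
first-chunk-as-baseline convention):

* **Jensen–Shannon divergence** between smoothed token frequency
  distributions, `JSD(P,Q) = KL(P‖M)/2 + KL(Q‖M)/2`, `M = (P+Q)/2`,
  base-2 logs so the value lives in `[0, 1]`. Distributions are built
  over the **union vocabulary** of all chunks (JSD is undefined on
  mismatched supports) with an additive smoothing of ε = 0.5 counts per
  cell (KL terms must stay finite on disjoint supports). Token counting
  is per occurrence by default, with a per-patient deduplication switch:
  occurrence counts and patient indicators are both defensible readings
  of "token frequency" for hospital event data, so both are supported
  and the default is documented rather than hidden.
* **Centroid cosine distance** between the chunk's and the reference's
  mean one-hot bag-of-events (or standardized feature vector).
* **PCA reconstruction error**: a component basis is fitted on the
  reference chunk only (centering/scaling learned on the reference;
  components cover 90% of reference variance by default) and every chunk
  is scored by the mean squared residual norm of projecting its rows
  onto that basis.
* **Autoencoder reconstruction error**: a single-hidden-layer ReLU
  autoencoder (bottleneck 16, full-batch Adam, 200 epochs, seeded,
  single-threaded) trained on the reference chunk; same scoring. With a
  linear activation it converges to the PCA subspace, which the tests
  exploit as an oracle.
* **Two-chunk classifier score**: label reference rows 0 and target rows
  1 and report stratified 5-fold cross-validated **balanced accuracy** of
  a ridge logistic model (glmnet, fixed λ = 0.01). ≈0.5 means the chunks
  are exchangeable; 1.0 means fully separable. Balanced accuracy was
  chosen because chunk sizes (and outcome classes) need not be balanced;
  the upstream literature plots an unspecified "classifier error", and
  balanced accuracy is the scale-free variant of that quantity.

The signal series covers **all** chunks, the reference included with its
self-comparison value (0 for JSD/centroid, the in-sample residual for the
reconstruction metrics, a random-split ≈0.5 for the classifier). Series
are min–max normalized for plotting; a constant series maps to all zeros
(the no-variation convention avoids 0/0).

### Flagging

`detect_drift()` implements a sequential k-standard-deviation rule
(default k = 2): the first `reference_window` values (default 3,
reference chunk included) form a baseline; each later value is flagged
when it exceeds `mean + k·SD` of the baseline; non-flagged values are
absorbed into the baseline, flagged ones never are. Design notes:

* Including the reference chunk's self-value in the baseline makes the
  threshold deliberately conservative for divergence-type signals (the
  baseline then spans "no drift at all" to "sampling noise"), which is
  what a monitoring loop wants under the null.
* Absorbing non-flagged values keeps the baseline growing, so a
  once-flagged sustained shift keeps flagging instead of inflating the
  baseline with drifted values.
* A zero-variance baseline (e.g. a hand-made constant series) falls back
  to flagging any value above the baseline mean, with a warning.

## Stage 2: initial characterization

Four trajectory tables, one value per chunk:

* outcome prevalence (with denominators; empty chunks are `NA`);
* per-chunk point-biserial Pearson (or Spearman) correlation of each
  feature with the outcome indicator (1 = category of interest). A
  feature constant within a chunk yields `NA`, **not** 0 — a zero would
  silently distort rankings;
* per-chunk normalized feature importance of a seeded random forest
  (50 CART trees, depth 3, Gini importance; permutation importance on
  out-of-bag rows by flag). No tree-ensemble package exists in the
  supported dependency set, so the forest is implemented in the package;
  it is scoped to importance at monitoring scale, not general learning;
* class-centroid drift: for each outcome class and for the overall
  population, the cosine distance between the group's one-hot centroid
  in each chunk and the same group's centroid in the reference chunk.
  Centroids are plain arithmetic means of one-hot rows (unnormalized) —
  the literal "average of each patient's features".

`top_k_trajectories()` ranks entities by absolute statistic (pooled mean
or a chosen chunk), with exact ties broken lexicographically so results
are reproducible.

## Stage 3: semantic characterization

The outcome is encoded as an *artificial token per (category, chunk)* —
`deceased@C01`, `deceased@C05`, ... — appended to each patient's token
sequence (high granularity, both outcome categories tokenized; survivors
can be dropped by flag) or attached as a node linked to each patient
(low granularity, after equal-width histogram discretization of
continuous attributes into 5 bins on the pooled range; interior bin
edges are left-closed/right-open, the top bin closed).

One **joint** skip-gram model (SGNS) is trained over all chunks so that
per-chunk outcome tokens share a vector space; training per-chunk models
would make cross-chunk cosine comparisons meaningless. For snapshot
cohorts the corpus is generated by seeded second-order `(p, q)` random
walks over the bipartite patient–attribute graph (`p = q = 1` by
default: plain uniform walks; the graph is unweighted membership).

Training defaults: dimension 64, window 10 (with word2vec's dynamic
window shrink this approximates whole-sequence context at typical
sequence lengths), 10 epochs, 10 negative samples, unigram^0.75 negative
sampling, linear learning-rate decay from 0.025, `min_count` 1 at desk
scale. Three details matter at clinical corpus sizes and were each
adopted after an identifiable estimation defect, not as tuning:

* sentences are re-shuffled (deterministically) every epoch — without
  this, the file's chunk order leaks into the geometry of the per-chunk
  outcome tokens and every delta acquires a spurious negative bias;
* frequent tokens are subsampled with word2vec's `t` rule at
  `t = 0.005` — the handful of stopword-like head tokens otherwise
  dominate the cosine geometry (hubness) and crowd out genuine movers;
  the web-corpus default `t = 1e-3` is far too aggressive for a
  20k-token corpus and would subsample the clinically interesting
  mid-frequency tokens themselves;
* the returned vectors are the Polyak average of the weights over the
  second half of training, which markedly reduces SGD noise in the
  similarity estimates.

The trainer is written in C++ with a private deterministic RNG and a
single thread: identical seed, identical vectors, on any machine.

**Vector choice.** The token vector used for similarity queries is the
*average of the input and output (context) matrices*. A pure
input–input cosine measures second-order similarity (tokens used in
similar contexts) and is a noisy estimator of token–outcome
co-occurrence at clinical corpus sizes (an outcome token occurs once per
patient). The averaged representation mixes in the input–output cross
terms that directly encode co-occurrence — the quantity the
similarity-change analysis is about — while keeping every token as a
single vector, so self-similarity is exactly 1 and all downstream
cosines are ordinary cosines. Averaging the two matrices is standard
practice in the embedding literature (GloVe reports summed vectors for
the same reason). Empirically this choice, not extra epochs, is what
makes token–outcome association shifts recoverable; training *longer*
actually degrades the cross-term signal as the space grows anisotropic,
which is why the epoch default stays at 10.

`similarity_change()` scores every token by
`Δ = cos(token, outcome@last) − cos(token, outcome@first)`, labels the
sign ("more similar" / "less similar"), sorts descending with ties broken
by token id, and `aggregate_by_chapter()` averages member deltas per
ICD-like chapter (unweighted mean — the natural default absent any
statement of how code-level values become chapter rows).

As a syntactic comparator, `tfidf_cluster_baseline()` clusters patients
by TF-IDF vectors (smooth idf, minimal value 1 for ubiquitous terms;
L2-normalized rows) with spectral clustering on the cosine affinity,
choosing k in 2–15 by mean silhouette, and reports top features and
per-chunk cluster frequencies. It exists to show what the semantic layer
adds; it shares no code path with the embedding route.

## The synthetic cohort generator

Credentialed clinical registries cannot ship with a package, so every
stage is exercised against a seeded generator whose defaults are the
stated world of the tests:

* 5 chunks × 500 patients; 100-token vocabulary in 10 chapters;
  Zipf(1.1) baseline token usage (heavy-tailed, like ICD code usage);
  2 + Poisson(8) events per patient; 20% baseline death prevalence (the
  death rate of hospitalized COVID-19 cohorts).
* The outcome is logistic in risk-token indicators (high granularity;
  default risk tokens are the Zipf ranks 11–13, whose ~15% per-patient
  prevalence matches the 5–30% range of common comorbidities — more
  frequent tokens behave like stopwords, rarer ones like rare diseases)
  or in standardized snapshot features (age, FiO2, CRP, sodium,
  hypertension), with the intercept calibrated per chunk by root-finding
  so the realized prevalence tracks its target.
* Drift scenarios compose four trajectory types (sudden step;
  incremental linear parameter ramp; gradual per-patient regime mixing —
  the "concepts interchange" reading; reoccurring on/off alternation)
  with four targets (token frequency, outcome prevalence, token–outcome
  association, numeric outliers).
* Numeric outliers default to 0.2% of patients at ~100 feature SDs: a
  "small number" of entry-error rows whose values sit orders of
  magnitude above typical values (a heart rate recorded as ~1600), which
  is the regime reconstruction-based metrics are sensitive to while
  frequency-based divergences are not.
* A class-conditional token-frequency scenario (e.g. only deceased
  patients' event mix shifts) is implemented by re-drawing the affected
  class's events *after* outcomes are assigned. This deliberately breaks
  the token→outcome logistic link for those patients — it is the only
  way to perturb `P(events | class)` alone — and is documented rather
  than hidden.
* Admission dates are uniform within each chunk's quarter; chunk
  assignment is their only use.

What the generator does **not** emulate: correlated comorbidity
structure, informative missingness, coding-practice artefacts, or any
real ICD hierarchy. A green recovery test therefore establishes that the
pipeline detects and attributes the *injected* mechanism at realistic
sizes — not that it would reproduce any particular finding on real
registry data.

## Numerical choices and degenerate inputs

* JSD inputs are validated to sum to 1 within 1e-6; distributions are
  stored with their smoothing ε and raw counts.
* Min–max normalization of a constant series returns zeros.
* A chunk with zero tokens is an error naming the chunk (with ε > 0 the
  smoothed distribution would otherwise be silently uniform).
* `n_components` above the reference rank is an error; fractional
  `n_components` picks the smallest basis reaching that variance share.
* Cross-validation folds that end up single-class are skipped with a
  warning; a fully single-class chunk skips the forest fit (`NA` column).
* Logistic intercept calibration brackets the root in ±30 log-odds.
* All stochastic components take an explicit integer seed; the pipeline
  derives per-stage seeds from the master seed with a fixed hash, so
  adding a stage never shifts another stage's stream.

## Scope and limitations

* The monitoring loop is realized as a batch re-run over an appended
  chunk, not a daemon.
* No streaming/active-learning detection, no label-based model
  monitoring beyond the two-chunk classifier, no SHAP-style
  explanations, no subword or contextual embeddings, and no causal
  claims: a similarity shift is a co-occurrence statement.
* Whether real event streams should be counted as occurrences or
  patient indicators is data-dependent; both are supported
  (`per_patient`), occurrences being the default.
* The embedding stage needs enough outcome events per chunk (roughly
  ≥50) for stable outcome-token vectors; below that, deltas are noise
  and the package will not warn you.
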