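# cohortshift

Detection and semantic characterization of temporal drifts in health
care cohorts.

Clinical data change under your feet: vaccination campaigns rewrite who
is hospitalized and who dies, treatment advances decouple diagnoses from
their historical lethality, coding practice changes what is recorded at
all. `cohortshift` is an R implementation of a three-stage workflow for
finding such drifts and explaining them:

1. **Detection.** The cohort is split into ordered temporal chunks and
   each chunk is compared with the reference (first) chunk by five
   complementary metrics: Jensen–Shannon divergence between smoothed
   token frequency distributions
   (`JSD(P,Q) = ½KL(P‖M) + ½KL(Q‖M)`, `M = (P+Q)/2`, base-2 logs so
   `JSD ∈ [0,1]`), centroid cosine distance
   (`1 − u·v / (‖u‖‖v‖)` between mean one-hot patient vectors), PCA and
   single-hidden-layer autoencoder reconstruction errors (basis/model fit
   on the reference chunk only), and the cross-validated balanced
   accuracy of a ridge classifier separating the two chunks (≈0.5 under
   no drift). Signals are min–max normalized
   (`(X − min X)/(max X − min X)`) and flagged by a sequential
   mean + k·SD rule (default k = 2).
2. **Initial characterization.** Outcome prevalence per chunk, per-chunk
   point-biserial Pearson/Spearman feature–outcome correlations, seeded
   random-forest feature importances (normalized to sum to 1 per chunk),
   and cosine drift of each outcome class's centroid against its
   reference-chunk centroid.
3. **Semantic characterization.** Each patient becomes a token sequence
   (events in temporal order, high granularity) or a node in a bipartite
   patient–attribute graph (snapshot data, after equal-width
   discretization); the outcome is encoded as one artificial token per
   temporal chunk (`deceased@C01`, `deceased@C06`, ...). One joint,
   seeded skip-gram model embeds everything in a shared space, and every
   clinical token is ranked by
   `Δ = cos(token, outcome@last) − cos(token, outcome@first)`,
   optionally aggregated by ICD-like chapter. A TF-IDF +
   spectral-clustering baseline is included as the syntactic comparator.

Because the registries this kind of analysis targets are credentialed, a
seeded synthetic cohort generator ships as a first-class module: Zipf
token vocabularies with chapters, logistic outcome models, and
injectable drifts of four trajectory types (sudden, incremental,
gradual, reoccurring) on four targets (token frequency, outcome
prevalence, token–outcome association, numeric outliers). Every
stochastic component is deterministic under a fixed seed.

## Worked example

Simulate a cohort of 3,000 patients in six chunks with two drifts
injected at chunk 4 — five tokens double their frequency, and the
previously neutral token `icd_014` becomes a strong mortality marker —
then run the full pipeline:

```r
library(cohortshift)

cfg <- cohort_config(
  n_patients_per_chunk = 500, n_chunks = 6, seed = 42,
  scenarios = list(
    drift_scenario("sudden", "token_frequency", 4, 2),
    drift_scenario("sudden", "token_outcome_association", 4, 4,
                   tokens = "icd_014")))
ds <- generate_high_granularity(cfg)
report <- run_pipeline(
  run_config(mode = "high", seed = 1,
             metrics = c("jsd", "centroid", "classifier")),
  dataset = ds)
print(report)
```

The report this prints (abridged):

```
## Detection

| metric | flagged chunks | max normalized signal |
|---|---|---|
| jsd | C04, C05, C06 | 1.000 |
| centroid | C04, C05, C06 | 1.000 |
| classifier | C04, C05, C06 | 1.000 |

## Initial characterization

- outcome prevalence by chunk: C01=0.192, C02=0.192, C03=0.208, ...
- top correlated features: icd_014, icd_013, icd_012, icd_011, ...

## Semantic characterization

Comparing outcome tokens of chunks C01 and C06.

| token | delta | direction |
|---|---|---|
| icd_010 | +0.554 | more similar |
| icd_014 | +0.448 | more similar |
| ...     |        |              |
```

Reading it: all three metrics first flag chunk `C04` — exactly the
injected onset. Stage 2 puts `icd_014` at the top of the
outcome-correlation ranking. Stage 3 shows `icd_014` among the tokens
that became most similar to the death outcome between the first and last
chunk (Δ = +0.45); the other top gainers are the frequency-drifted
tokens (e.g. `icd_010`), whose tripled presence mechanically raises
their co-occurrence with the outcome. On a real cohort this table is
where "mortality shifted toward younger, severely ill patients" -style
findings surface.

## Command line

```sh
inst/cli/cohortshift simulate --mode high --n-per-chunk 500 \
    --n-chunks 6 --seed 42 --out cohort.csv
inst/cli/cohortshift detect --input cohort.csv --mode high \
    --metric jsd,centroid --out signals.csv
inst/cli/cohortshift run --input cohort.csv --mode high --out results/
```

Subcommands: `simulate`, `detect`, `characterize`, `semantic`, `run`;
exit codes 0/1/2 (ok / validation error / runtime error).

## Documentation

The methods vignette (`vignettes/temporal-drift-methods.Rmd`) documents
the model and its assumptions, every tunable parameter with its default
and rationale, what the synthetic generator does and does not emulate,
numerical edge-case conventions, and known limitations.
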