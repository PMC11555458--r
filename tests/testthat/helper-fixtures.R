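# Shared in-code fixtures: tiny cohorts built by hand and small synthetic
# configurations used across test files.

# Three patients, two chunks, hand-written events.
tiny_high_dataset <- function() {
  patients <- data.frame(
    patient_id = c("p1", "p2", "p3"),
    chunk = c("A", "A", "B"),
    outcome = c("deceased", "discharged", "deceased"),
    stringsAsFactors = FALSE)
  events <- data.frame(
    patient_id = c("p1", "p1", "p2", "p3", "p3", "p3"),
    order = c(1, 2, 1, 1, 2, 3),
    token = c("dx_a", "dx_b", "dx_a", "dx_b", "dx_c", "dx_a"),
    stringsAsFactors = FALSE)
  chunked_dataset(patients, mode = "high", events = events)
}

tiny_low_dataset <- function(n = 40, seed = 42) {
  withr::with_seed(seed, {
    patients <- data.frame(
      patient_id = sprintf("p%02d", seq_len(n)),
      chunk = rep(c("A", "B"), each = n / 2),
      outcome = sample(c("deceased", "discharged"), n, TRUE, c(0.3, 0.7)),
      stringsAsFactors = FALSE)
    features <- data.frame(
      patient_id = patients$patient_id,
      age = rnorm(n, 60, 15),
      crp = rlnorm(n, log(50), 0.5),
      sex = sample(c("male", "female"), n, TRUE),
      stringsAsFactors = FALSE)
    chunked_dataset(patients, mode = "low", features = features)
  })
}

quick_config <- function(seed = 1L, ...) {
  cohort_config(n_patients_per_chunk = 150L, n_chunks = 4L,
                vocabulary_size = 60L, n_chapters = 6L, seed = seed, ...)
}
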