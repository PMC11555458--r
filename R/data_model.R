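## Data model: chunked cohorts, ingestion, chunk assignment and
## per-chunk token frequency distributions.

#' Construct a chunked cohort dataset
#'
#' The central container of the package: a patient cohort split into ordered
#' temporal chunks. Two granularity modes are supported. In `"high"`
#' (event-level) mode each patient carries a temporally ordered sequence of
#' discrete event tokens (ICD codes, consumed items, ...). In `"low"`
#' (snapshot) mode each patient is a single row of mixed numeric/categorical
#' attributes. Both modes carry a categorical outcome per patient.
#'
#' @param patients data.frame with columns `patient_id`, `chunk`, `outcome`.
#' @param mode `"high"` or `"low"` temporal granularity.
#' @param events data.frame with columns `patient_id`, `order`, `token`
#'   (high mode, or a tokenized low-granularity cohort).
#' @param features data.frame with `patient_id` plus one column per
#'   attribute (low mode). May include an `admission_date` column.
#' @param chunks ordered character vector of chunk labels; defaults to the
#'   sorted unique labels present in `patients`.
#' @param reference_chunk the baseline chunk all others are compared
#'   against; defaults to the first chunk.
#' @param chapter_map optional named character vector mapping event tokens
#'   to chapter labels (ICD-chapter-like grouping).
#' @param outcome_levels declared outcome categories; defaults to observed.
#' @param n_rejected count of input rows rejected during ingestion.
#' @param truth optional list with the generator's ground-truth drift
#'   schedule (kept for recovery experiments).
#' @return An object of class `chunked_dataset`.
#' @export
chunked_dataset <- function(patients, mode = c("high", "low"),
                            events = NULL, features = NULL,
                            chunks = NULL, reference_chunk = NULL,
                            chapter_map = NULL, outcome_levels = NULL,
                            n_rejected = 0L, truth = NULL) {
  mode <- match.arg(mode)
  assert(is.data.frame(patients) &&
           all(c("patient_id", "chunk", "outcome") %in% names(patients)),
         "`patients` must have columns patient_id, chunk, outcome")
  patients$patient_id <- as.character(patients$patient_id)
  patients$chunk <- as.character(patients$chunk)
  patients$outcome <- as.character(patients$outcome)
  assert(!anyDuplicated(patients$patient_id),
         "duplicated patient_id in `patients`")
  if (is.null(chunks)) chunks <- sort(unique(patients$chunk))
  assert(length(chunks) > 0, "cohort has no chunks")
  assert(all(patients$chunk %in% chunks),
         "every record's chunk label must appear in `chunks`")
  if (is.null(reference_chunk)) reference_chunk <- chunks[[1L]]
  assert(reference_chunk %in% chunks, "unknown reference chunk")
  if (mode == "high") {
    assert(is.data.frame(events) &&
             all(c("patient_id", "token") %in% names(events)),
           "high-granularity mode needs an `events` table (patient_id, token)")
  } else {
    assert(is.data.frame(features) && "patient_id" %in% names(features),
           "low-granularity mode needs a `features` table")
  }
  if (!is.null(events)) {
    events$patient_id <- as.character(events$patient_id)
    events$token <- as.character(events$token)
    assert(all(nzchar(events$token)), "empty event token")
    assert(!any(grepl(OUTCOME_DELIM, events$token, fixed = TRUE)),
           "event tokens must not contain the reserved delimiter '",
           OUTCOME_DELIM, "'")
    assert(all(events$patient_id %in% patients$patient_id),
           "events reference unknown patients")
    if (!"order" %in% names(events)) events$order <- seq_len(nrow(events))
    events <- events[order(match(events$patient_id, patients$patient_id),
                           events$order), , drop = FALSE]
    rownames(events) <- NULL
  }
  if (is.null(outcome_levels)) outcome_levels <- sort(unique(patients$outcome))
  assert(all(patients$outcome %in% outcome_levels),
         "outcome labels outside declared categories: ",
         paste(setdiff(patients$outcome, outcome_levels), collapse = ", "))
  structure(
    list(mode = mode, chunks = as.character(chunks),
         reference_chunk = reference_chunk,
         patients = patients, events = events, features = features,
         chapter_map = chapter_map, outcome_levels = outcome_levels,
         n_rejected = as.integer(n_rejected), truth = truth),
    class = "chunked_dataset")
}

#' @export
print.chunked_dataset <- function(x, ...) {
  cat(sprintf("<chunked_dataset> %s granularity: %d patients, %d chunks (%s)\n",
              x$mode, nrow(x$patients), length(x$chunks),
              paste(x$chunks, collapse = ", ")))
  cat(sprintf("  reference chunk: %s; outcomes: %s\n", x$reference_chunk,
              paste(x$outcome_levels, collapse = "/")))
  if (!is.null(x$events)) {
    cat(sprintf("  events: %d rows, %d distinct tokens\n", nrow(x$events),
                length(unique(x$events$token))))
  }
  if (!is.null(x$features)) {
    cat(sprintf("  features: %s\n",
                paste(setdiff(names(x$features), "patient_id"),
                      collapse = ", ")))
  }
  if (x$n_rejected > 0) cat(sprintf("  rejected input rows: %d\n", x$n_rejected))
  invisible(x)
}

#' Load a cohort from a delimited file
#'
#' Reads a CSV and assembles a [chunked_dataset()]. In high-granularity mode
#' the file has one row per (patient, event); in low-granularity mode one
#' row per patient. Rows missing the patient id or the chunk label are
#' rejected and counted, not fatal.
#'
#' @param path path to a CSV file with a header row.
#' @param schema named list mapping roles to column names. Required roles:
#'   `patient_id`, `chunk`, `outcome`; high mode additionally `event` and
#'   optionally `order`; low mode optionally `features` (character vector,
#'   default: all remaining columns) and `admission_date`.
#' @param mode `"high"` or `"low"`.
#' @param outcome_levels optional declared outcome categories; unknown
#'   labels in the file raise a validation error listing the offenders.
#' @param ... passed to [chunked_dataset()].
#' @return A validated `chunked_dataset`. The rejected-row count is in
#'   `$n_rejected`.
#' @export
load_dataset <- function(path, schema, mode = c("high", "low"),
                         outcome_levels = NULL, ...) {
  mode <- match.arg(mode)
  assert(file.exists(path), "file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  assert(nrow(df) > 0, "empty input file: ", path)
  need <- c("patient_id", "chunk", "outcome",
            if (mode == "high") "event")
  for (role in need) {
    col <- schema[[role]]
    assert(!is.null(col), "schema is missing the `", role, "` role")
    assert(col %in% names(df),
           "schema error: column `", col, "` (role ", role,
           ") not present in ", path)
  }
  pid <- as.character(df[[schema$patient_id]])
  chk <- as.character(df[[schema$chunk]])
  bad <- is.na(pid) | !nzchar(pid) | is.na(chk) | !nzchar(chk)
  n_rejected <- sum(bad)
  df <- df[!bad, , drop = FALSE]
  pid <- pid[!bad]; chk <- chk[!bad]
  assert(nrow(df) > 0, "no valid rows after rejecting ", n_rejected)
  out <- as.character(df[[schema$outcome]])
  if (!is.null(outcome_levels)) {
    unknown <- setdiff(unique(out[!is.na(out)]), outcome_levels)
    assert(length(unknown) == 0,
           "unknown outcome categories: ", paste(unknown, collapse = ", "))
  }
  if (mode == "high") {
    ord <- if (!is.null(schema$order) && schema$order %in% names(df)) {
      df[[schema$order]]
    } else {
      seq_len(nrow(df))   # ties broken by file order
    }
    o <- order(pid, ord, seq_len(nrow(df)))
    events <- data.frame(patient_id = pid[o], order = ord[o],
                         token = as.character(df[[schema$event]])[o],
                         stringsAsFactors = FALSE)
    pat <- df[!duplicated(pid), , drop = FALSE]
    patients <- data.frame(patient_id = pid[!duplicated(pid)],
                           chunk = chk[!duplicated(pid)],
                           outcome = out[!duplicated(pid)],
                           stringsAsFactors = FALSE)
    chunked_dataset(patients, mode = "high", events = events,
                    outcome_levels = outcome_levels,
                    n_rejected = n_rejected, ...)
  } else {
    patients <- data.frame(patient_id = pid, chunk = chk, outcome = out,
                           stringsAsFactors = FALSE)
    feat_cols <- schema$features %||%
      setdiff(names(df), unlist(schema[c("patient_id", "chunk", "outcome")]))
    missing_cols <- setdiff(feat_cols, names(df))
    assert(length(missing_cols) == 0,
           "schema error: feature columns absent: ",
           paste(missing_cols, collapse = ", "))
    features <- cbind(data.frame(patient_id = pid, stringsAsFactors = FALSE),
                      df[, feat_cols, drop = FALSE])
    if (!is.null(schema$admission_date) &&
        schema$admission_date %in% names(df)) {
      features$admission_date <- as.Date(df[[schema$admission_date]])
    }
    chunked_dataset(patients, mode = "low", features = features,
                    outcome_levels = outcome_levels,
                    n_rejected = n_rejected, ...)
  }
}

#' Write a cohort back to CSV
#'
#' Canonical re-export: `load_dataset()` on the written file round-trips to
#' an equal dataset. High mode writes one row per (patient, event); low mode
#' one row per patient.
#'
#' @param dataset a `chunked_dataset`.
#' @param path output CSV path.
#' @return `path`, invisibly. The schema needed to re-load is attached as
#'   the `"schema"` attribute.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "chunked_dataset"))
  if (dataset$mode == "high") {
    ev <- dataset$events
    m <- match(ev$patient_id, dataset$patients$patient_id)
    out <- data.frame(patient_id = ev$patient_id,
                      chunk = dataset$patients$chunk[m],
                      order = ev$order, event = ev$token,
                      outcome = dataset$patients$outcome[m],
                      stringsAsFactors = FALSE)
    schema <- list(patient_id = "patient_id", chunk = "chunk",
                   order = "order", event = "event", outcome = "outcome")
  } else {
    m <- match(dataset$features$patient_id, dataset$patients$patient_id)
    out <- cbind(dataset$features[, "patient_id", drop = FALSE],
                 chunk = dataset$patients$chunk[m],
                 outcome = dataset$patients$outcome[m],
                 dataset$features[, setdiff(names(dataset$features),
                                            "patient_id"), drop = FALSE])
    schema <- list(patient_id = "patient_id", chunk = "chunk",
                   outcome = "outcome",
                   features = setdiff(names(dataset$features),
                                      c("patient_id", "admission_date")),
                   admission_date = if ("admission_date" %in%
                                          names(dataset$features))
                     "admission_date")
  }
  utils::write.csv(out, path, row.names = FALSE)
  attr(path, "schema") <- schema
  invisible(path)
}

#' Assign patient records to temporal chunks by admission date
#'
#' Bins records into half-open intervals
#' `[boundaries[i], boundaries[i+1])`: a date exactly on a boundary goes to
#' the later chunk. Records outside all intervals are dropped and counted.
#'
#' @param records data.frame with at least `patient_id`, `outcome` and an
#'   admission-date column.
#' @param boundaries strictly increasing Date vector of n+1 cutpoints
#'   delimiting n chunks.
#' @param labels optional chunk labels (length `length(boundaries) - 1`).
#' @param date_col name of the admission-date column.
#' @param mode granularity mode of the resulting dataset.
#' @param ... passed to [chunked_dataset()].
#' @return A `chunked_dataset`; dropped-record count in `$n_rejected`.
#' @export
assign_chunks <- function(records, boundaries, labels = NULL,
                          date_col = "admission_date",
                          mode = c("low", "high"), ...) {
  mode <- match.arg(mode)
  boundaries <- as.Date(boundaries)
  assert(length(boundaries) >= 2 && !is.unsorted(boundaries, strictly = TRUE),
         "`boundaries` must be strictly increasing")
  assert(date_col %in% names(records), "no `", date_col, "` column")
  n_chunks <- length(boundaries) - 1L
  if (is.null(labels)) labels <- sprintf("C%02d", seq_len(n_chunks))
  assert(length(labels) == n_chunks, "need one label per interval")
  d <- as.Date(records[[date_col]])
  idx <- findInterval(as.numeric(d), as.numeric(boundaries),
                      rightmost.closed = FALSE, left.open = FALSE)
  keep <- !is.na(idx) & idx >= 1L & idx <= n_chunks
  dropped <- sum(!keep)
  kept <- records[keep, , drop = FALSE]
  patients <- data.frame(patient_id = as.character(kept$patient_id),
                         chunk = labels[idx[keep]],
                         outcome = as.character(kept$outcome),
                         stringsAsFactors = FALSE)
  feats <- kept[, setdiff(names(kept), c("chunk", "outcome")), drop = FALSE]
  chunked_dataset(patients, mode = mode,
                  features = if (mode == "low") feats,
                  events = if (mode == "high") kept,
                  chunks = labels, n_rejected = dropped, ...)
}

#' Construct a smoothed frequency distribution over a vocabulary
#'
#' @param counts named numeric vector of token counts, or unnamed counts
#'   aligned with `vocabulary`.
#' @param vocabulary ordered token vector; defaults to `names(counts)`.
#' @param epsilon additive smoothing pseudo-count applied to every
#'   vocabulary cell before normalization (default 0.5 so that divergences
#'   stay finite on disjoint supports).
#' @return A `freq_dist` object: list(vocabulary, probabilities, counts,
#'   smoothing_epsilon).
#' @export
freq_dist <- function(counts, vocabulary = NULL, epsilon = 0.5) {
  if (is.null(vocabulary)) vocabulary <- names(counts)
  assert(!is.null(vocabulary), "need a vocabulary")
  assert(epsilon >= 0, "epsilon must be nonnegative")
  full <- setNames(numeric(length(vocabulary)), vocabulary)
  if (!is.null(names(counts))) {
    unknown <- setdiff(names(counts), vocabulary)
    assert(length(unknown) == 0, "tokens outside vocabulary: ",
           paste(utils::head(unknown, 5), collapse = ", "))
    full[names(counts)] <- counts
  } else {
    assert(length(counts) == length(vocabulary),
           "unnamed counts must match vocabulary length")
    full[] <- counts
  }
  sm <- full + epsilon
  tot <- sum(sm)
  assert(tot > 0, "all-zero counts with epsilon = 0")
  p <- sm / tot
  structure(list(vocabulary = vocabulary, probabilities = unname(p),
                 counts = unname(full), smoothing_epsilon = epsilon),
            class = "freq_dist")
}

#' @export
print.freq_dist <- function(x, ...) {
  cat(sprintf("<freq_dist> %d tokens, epsilon = %g, total count %g\n",
              length(x$vocabulary), x$smoothing_epsilon, sum(x$counts)))
  invisible(x)
}

#' Per-chunk token frequency distributions
#'
#' Counts token occurrences per chunk over a common vocabulary and returns a
#' smoothed probability distribution per chunk. Low-granularity cohorts must
#' be tokenized first (see [discretize_continuous()]).
#'
#' @param dataset a `chunked_dataset` with an events table.
#' @param vocabulary_policy `"union"` (default): vocabulary is the union of
#'   tokens over all chunks; `"reference_only"`: restricted to tokens seen
#'   in the reference chunk.
#' @param epsilon additive smoothing per vocabulary cell.
#' @param per_patient if `TRUE`, count each (patient, token) pair at most
#'   once (patient indicators) instead of raw occurrences.
#' @return Named list (one `freq_dist` per chunk, in chunk order).
#' @export
chunk_frequencies <- function(dataset,
                              vocabulary_policy = c("union", "reference_only"),
                              epsilon = 0.5, per_patient = FALSE) {
  stopifnot(inherits(dataset, "chunked_dataset"))
  vocabulary_policy <- match.arg(vocabulary_policy)
  assert(!is.null(dataset$events),
         "no event tokens: tokenize low-granularity data first ",
         "(discretize_continuous)")
  ev <- dataset$events
  m <- match(ev$patient_id, dataset$patients$patient_id)
  ev$chunk <- dataset$patients$chunk[m]
  if (per_patient) {
    ev <- ev[!duplicated(ev[c("patient_id", "token")]), , drop = FALSE]
  }
  vocab <- if (vocabulary_policy == "union") {
    sort(unique(ev$token))
  } else {
    sort(unique(ev$token[ev$chunk == dataset$reference_chunk]))
  }
  res <- lapply(dataset$chunks, function(ch) {
    tok <- ev$token[ev$chunk == ch]
    tok <- tok[tok %in% vocab]
    assert(length(tok) > 0 || epsilon > 0,
           "degenerate chunk with zero tokens: ", ch)
    tab <- table(factor(tok, levels = vocab))
    freq_dist(as.numeric(tab), vocabulary = vocab, epsilon = epsilon)
  })
  names(res) <- dataset$chunks
  res
}

#' One-hot bag-of-events matrix
#'
#' Patient-by-token indicator matrix (order-free representation used by the
#' centroid, PCA, autoencoder and classifier drift metrics and by the
#' initial-characterization centroid trajectories).
#'
#' @param dataset a `chunked_dataset` with events.
#' @param vocabulary optional fixed column vocabulary (default: union).
#' @param binary if `TRUE` (default) indicators, else occurrence counts.
#' @return Numeric matrix, rows named by patient_id, columns by token.
#' @export
bag_of_events <- function(dataset, vocabulary = NULL, binary = TRUE) {
  stopifnot(inherits(dataset, "chunked_dataset"))
  assert(!is.null(dataset$events), "dataset has no event tokens")
  ev <- dataset$events
  if (is.null(vocabulary)) vocabulary <- sort(unique(ev$token))
  pid <- dataset$patients$patient_id
  i <- match(ev$patient_id, pid)
  j <- match(ev$token, vocabulary)
  keep <- !is.na(j)
  mat <- matrix(0, nrow = length(pid), ncol = length(vocabulary),
                dimnames = list(pid, vocabulary))
  if (any(keep)) {
    tab <- table(i[keep], j[keep])
    mat[cbind(as.integer(rownames(tab))[row(tab)],
              as.integer(colnames(tab))[col(tab)])] <- as.numeric(tab)
  }
  if (binary) mat[mat > 0] <- 1
  mat
}

#' Numeric feature matrix for a cohort
#'
#' High granularity: the one-hot bag-of-events. Low granularity: numeric
#' attribute columns as-is plus one-hot-encoded categorical attributes
#' (admission dates are excluded).
#'
#' @param dataset a `chunked_dataset`.
#' @param vocabulary optional fixed vocabulary for high mode.
#' @return Numeric matrix with one row per patient (rownames = patient_id).
#' @export
feature_matrix <- function(dataset, vocabulary = NULL) {
  stopifnot(inherits(dataset, "chunked_dataset"))
  if (dataset$mode == "high" || is.null(dataset$features)) {
    return(bag_of_events(dataset, vocabulary = vocabulary))
  }
  f <- dataset$features
  m <- match(dataset$patients$patient_id, f$patient_id)
  f <- f[m, , drop = FALSE]
  cols <- setdiff(names(f), c("patient_id", "admission_date"))
  parts <- lapply(cols, function(cn) {
    v <- f[[cn]]
    if (is.numeric(v)) {
      matrix(v, ncol = 1, dimnames = list(NULL, cn))
    } else {
      lev <- sort(unique(as.character(v)))
      out <- sapply(lev, function(l) as.numeric(as.character(v) == l))
      colnames(out) <- paste0(cn, "=", lev)
      out
    }
  })
  mat <- do.call(cbind, parts)
  rownames(mat) <- dataset$patients$patient_id
  mat
}

## Rows of `mat` belonging to one chunk.
chunk_rows <- function(dataset, chunk) {
  dataset$patients$patient_id[dataset$patients$chunk == chunk]
}
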