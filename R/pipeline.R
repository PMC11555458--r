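## End-to-end orchestration: detection -> initial characterization ->
## semantic characterization, with the semantic stage gated on a detected
## drift, plus artifact writing and a machine-readable run report.

#' Build a run configuration
#'
#' @param input path to a cohort CSV (or `NULL` when `dataset` given).
#' @param mode `"high"` or `"low"`.
#' @param schema column-role mapping for [load_dataset()].
#' @param reference_chunk optional override of the baseline chunk.
#' @param steps subset of `c("detect", "characterize", "semantic")`.
#' @param metrics detection metrics to run.
#' @param outcome_category outcome category of interest.
#' @param k_sd,reference_window flagging policy.
#' @param seed master seed; every stochastic stage derives its own from it.
#' @param out_dir artifact directory (`NULL`: nothing written).
#' @param force run the semantic stage even without a detection flag.
#' @param params optional per-stage parameter lists (`detect`,
#'   `characterize`, `semantic`) forwarded to the stage functions.
#' @return A `run_config` object.
#' @export
run_config <- function(input = NULL, mode = c("high", "low"),
                       schema = NULL, reference_chunk = NULL,
                       steps = c("detect", "characterize", "semantic"),
                       metrics = c("jsd", "centroid", "pca",
                                   "autoencoder", "classifier"),
                       outcome_category = "deceased", k_sd = 2,
                       reference_window = NULL, seed = 1L, out_dir = NULL,
                       force = FALSE, params = list()) {
  mode <- match.arg(mode)
  steps <- match.arg(steps, several.ok = TRUE)
  structure(list(input = input, mode = mode, schema = schema,
                 reference_chunk = reference_chunk, steps = steps,
                 metrics = metrics, outcome_category = outcome_category,
                 k_sd = k_sd, reference_window = reference_window,
                 seed = as.integer(seed), out_dir = out_dir,
                 force = isTRUE(force), params = params),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @export
read_run_config <- function(path) {
  assert(file.exists(path), "config file not found: ", path)
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Run the full drift-analysis pipeline
#'
#' Executes the requested stages in order detection -> initial
#' characterization -> semantic characterization. The semantic stage is
#' skipped (with a note in the report) when detection raised no flag,
#' unless `force = TRUE` in the config — no drift, nothing to explain.
#'
#' @param config a [run_config()].
#' @param dataset optionally, an already-loaded `chunked_dataset`
#'   (bypasses `config$input`).
#' @return A `run_report` list: config echo, per-stage results, flagged
#'   chunks, top trajectories and top similarity deltas. When
#'   `config$out_dir` is set, tidy CSVs per stage plus `report.json` and a
#'   reproducible `config.json` snapshot are written there.
#' @export
run_pipeline <- function(config, dataset = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(dataset)) {
    assert(!is.null(config$input), "config has no input and no dataset given")
    dataset <- load_dataset(config$input, config$schema, config$mode)
  }
  if (!is.null(config$reference_chunk)) {
    assert(config$reference_chunk %in% dataset$chunks,
           "unknown reference chunk: ", config$reference_chunk)
    dataset$reference_chunk <- config$reference_chunk
  }
  report <- list(config = unclass(config),
                 n_patients = nrow(dataset$patients),
                 chunks = dataset$chunks,
                 reference_chunk = dataset$reference_chunk,
                 warnings = character())
  note <- function(...) {
    report$warnings <<- c(report$warnings, paste0(...))
  }

  signals <- NULL
  if ("detect" %in% config$steps) {
    args <- c(list(dataset = dataset, metrics = config$metrics,
                   seed = derive_seed(config$seed, "detect"),
                   k_sd = config$k_sd,
                   reference_window = config$reference_window),
              config$params$detect %||% list())
    signals <- withCallingHandlers(
      do.call(detect_all, args),
      warning = function(w) {
        note("detect: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    report$detection <- lapply(signals, function(s) {
      list(metric = s$metric_name, raw = s$raw_values,
           normalized = s$normalized_values, flags = s$flags,
           flagged_chunks = s$chunk_labels[s$flags])
    })
    report$flagged_chunks <- sort(unique(unlist(
      lapply(signals, function(s) s$chunk_labels[s$flags]))))
  }

  if ("characterize" %in% config$steps) {
    prev <- outcome_prevalence_over_time(dataset, config$outcome_category)
    corr <- correlation_over_time(dataset,
                                  outcome_category = config$outcome_category)
    imp <- feature_importance_over_time(
      dataset, outcome_category = config$outcome_category,
      seed = derive_seed(config$seed, "characterize"))
    cdrift <- class_centroid_drift(dataset)
    report$characterization <- list(
      prevalence = as.data.frame(prev), correlation = as.data.frame(corr),
      importance = as.data.frame(imp), centroid = as.data.frame(cdrift),
      top_features = top_k_trajectories(corr,
                                        min(6L, length(corr$entity))))
  }

  if ("semantic" %in% config$steps) {
    has_flags <- length(report$flagged_chunks %||% character()) > 0
    if (!has_flags && !config$force && "detect" %in% config$steps) {
      report$semantic <- list(skipped = TRUE,
                              reason = "no drift flagged; use force to override")
    } else {
      sem_seed <- derive_seed(config$seed, "semantic")
      sp <- config$params$semantic %||% list()
      if (dataset$mode == "high") {
        corpus <- build_sequence_corpus(dataset)
        emb <- train_sequence_embeddings(
          corpus, dim = sp$dim %||% 64L, window = sp$window %||% 10L,
          epochs = sp$epochs %||% 10L, seed = sem_seed)
        tokens <- NULL
      } else {
        tokenized <- discretize_continuous(dataset,
                                           n_bins = sp$n_bins %||% 5L)
        graph <- build_patient_graph(tokenized)
        emb <- train_graph_embeddings(graph, dim = sp$dim %||% 64L,
                                      seed = sem_seed)
        tokens <- intersect(unique(tokenized$events$token),
                            rownames(emb$vectors))
      }
      first <- dataset$reference_chunk
      last <- dataset$chunks[length(dataset$chunks)]
      deltas <- similarity_change(emb, config$outcome_category, first,
                                  last, tokens = tokens,
                                  chapter_map = dataset$chapter_map)
      chapters <- if (!is.null(dataset$chapter_map)) {
        aggregate_by_chapter(deltas)
      }
      report$semantic <- list(skipped = FALSE, first_chunk = first,
                              last_chunk = last, deltas = deltas,
                              chapters = chapters,
                              top_deltas = utils::head(deltas, 10))
    }
  }

  class(report) <- "run_report"
  if (!is.null(config$out_dir)) write_report_artifacts(report, config)
  report
}

write_report_artifacts <- function(report, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$detection)) {
    sig_df <- do.call(rbind, lapply(names(report$detection), function(m) {
      d <- report$detection[[m]]
      data.frame(metric = m, chunk = report$chunks, raw = d$raw,
                 normalized = d$normalized, flagged = d$flags)
    }))
    utils::write.csv(sig_df, file.path(config$out_dir, "signals.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$characterization)) {
    for (nm in c("prevalence", "correlation", "importance", "centroid")) {
      utils::write.csv(report$characterization[[nm]],
                       file.path(config$out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  if (!is.null(report$semantic) && !isTRUE(report$semantic$skipped)) {
    utils::write.csv(report$semantic$deltas,
                     file.path(config$out_dir, "deltas.csv"),
                     row.names = FALSE)
    if (!is.null(report$semantic$chapters)) {
      utils::write.csv(report$semantic$chapters,
                       file.path(config$out_dir, "chapters.csv"),
                       row.names = FALSE)
    }
  }
  jsonlite::write_json(report_summary(report),
                       file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  cfg <- unclass(config)
  cfg$params <- NULL
  jsonlite::write_json(cfg, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(NULL)
}

## JSON-safe summary of a run report (drops bulky tables).
report_summary <- function(report) {
  list(
    n_patients = report$n_patients, chunks = report$chunks,
    reference_chunk = report$reference_chunk,
    flagged_chunks = report$flagged_chunks %||% character(),
    detection = lapply(report$detection %||% list(), function(d)
      list(raw = d$raw, normalized = d$normalized,
           flagged_chunks = d$flagged_chunks)),
    top_features = report$characterization$top_features,
    semantic_skipped = report$semantic$skipped %||% NA,
    top_deltas = if (!is.null(report$semantic$top_deltas))
      report$semantic$top_deltas,
    warnings = report$warnings)
}

#' @export
print.run_report <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}

#' Render a run report as markdown text
#'
#' @param report a `run_report`.
#' @return Character vector of markdown lines.
#' @export
render_report <- function(report) {
  stopifnot(inherits(report, "run_report"))
  lines <- c("# Temporal drift analysis report", "",
             sprintf("- patients: %d", report$n_patients),
             sprintf("- chunks: %s", paste(report$chunks, collapse = ", ")),
             sprintf("- reference chunk: %s", report$reference_chunk))
  if (!is.null(report$detection)) {
    lines <- c(lines, "", "## Detection", "",
               "| metric | flagged chunks | max normalized signal |",
               "|---|---|---|")
    for (m in names(report$detection)) {
      d <- report$detection[[m]]
      lines <- c(lines, sprintf(
        "| %s | %s | %.3f |", m,
        if (length(d$flagged_chunks)) paste(d$flagged_chunks,
                                            collapse = ", ") else "none",
        max(d$normalized)))
    }
  }
  if (!is.null(report$characterization)) {
    prev <- report$characterization$prevalence
    lines <- c(lines, "", "## Initial characterization", "",
               sprintf("- outcome prevalence by chunk: %s",
                       paste(sprintf("%s=%.3f", prev$chunk, prev$value),
                             collapse = ", ")),
               sprintf("- top correlated features: %s",
                       paste(report$characterization$top_features,
                             collapse = ", ")))
  }
  if (!is.null(report$semantic)) {
    lines <- c(lines, "", "## Semantic characterization", "")
    if (isTRUE(report$semantic$skipped)) {
      lines <- c(lines, sprintf("_skipped_ (%s)", report$semantic$reason))
    } else {
      top <- utils::head(report$semantic$deltas, 5)
      bottom <- utils::tail(report$semantic$deltas, 5)
      lines <- c(lines,
                 sprintf("Comparing outcome tokens of chunks %s and %s.",
                         report$semantic$first_chunk,
                         report$semantic$last_chunk), "",
                 "| token | delta | direction |", "|---|---|---|",
                 sprintf("| %s | %+.3f | %s |", top$token_id, top$delta,
                         top$direction),
                 sprintf("| %s | %+.3f | %s |", bottom$token_id,
                         bottom$delta, bottom$direction))
    }
  }
  if (length(report$warnings)) {
    lines <- c(lines, "", "## Warnings", "",
               paste0("- ", report$warnings))
  }
  lines
}
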