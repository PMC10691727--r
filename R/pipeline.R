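# End-to-end annotation runner: ingest -> anchors -> topology ->
# classification -> conservation -> motifs/checklist, collected into one
# per-sequence report.

pipeline_defaults <- function() {
  list(
    sequences = NULL,        # FASTA path or list of protein_records
    alignment = NULL,        # alignment path or alignment_block
    alignment_dialect = "aligned-fasta",
    architecture = "single-domain",
    fixture = NULL,          # similarity fixture path or object (optional)
    group_labels = NULL,     # named character vector (optional)
    h_min = 0.95,
    min_gap = 15L,
    max_gap = 90L,
    tm_window = 19L,
    tm_threshold = 1.6,
    tm_min_len = 15L,
    run_conservation = TRUE,
    run_motifs = TRUE,
    run_checklist = TRUE,
    output_dir = NULL,
    seed = 1L
  )
}

#' Validate a pipeline configuration
#'
#' Unknown keys are rejected by name; every parameter has a default.
#'
#' @param ... Configuration overrides (see `cytb561anno:::pipeline_defaults()`
#'   for the full key set).
#' @return A validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- pipeline_defaults()
  user <- list(...)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, user)
  if (!cfg$architecture %in% c("single-domain", "cybdom")) {
    stop("configuration key 'architecture' must be \"single-domain\" or \"cybdom\"")
  }
  for (key in c("h_min", "tm_threshold")) {
    if (!is.numeric(cfg[[key]]) || length(cfg[[key]]) != 1L) {
      stop(sprintf("configuration key '%s' must be a single number", key))
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the annotation pipeline
#'
#' Stages run in dependency order: sequence/alignment ingest, histidine
#' anchoring, hydropathy topology with sidedness, optional fixture-based
#' best-human-match classification, conservation profiling, motif scans
#' (C-terminal dileucine signals, KXXXXKXH loop site) and the
#' ferric-reductase checklist. Per-sequence stage failures are recorded in
#' the report rather than aborting the run.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `annotation_report`: `sequences` (per-sequence
#'   result lists), `anchors`, `conservation`, `summary` data frame,
#'   `errors`, and `metadata` (parameters and seed, sufficient to re-run).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) {
    stop("'config' must come from pipeline_config()")
  }
  if (is.null(config$sequences)) stop("configuration key 'sequences' is required")
  records <- if (is.character(config$sequences)) {
    read_sequences(config$sequences)
  } else {
    config$sequences
  }
  aln <- if (is.null(config$alignment)) {
    stop("configuration key 'alignment' is required (anchor detection is alignment-based)")
  } else if (is.character(config$alignment)) {
    read_alignment(config$alignment, config$alignment_dialect)
  } else {
    config$alignment
  }
  set.seed(config$seed)
  errors <- list()
  note <- function(id, stage, e) {
    errors[[length(errors) + 1L]] <<- list(id = id, stage = stage,
                                           message = conditionMessage(e))
    NULL
  }
  map <- find_histidine_anchors(aln, h_min = config$h_min,
                                min_gap = config$min_gap,
                                max_gap = config$max_gap)
  conservation <- if (isTRUE(config$run_conservation)) {
    list(logo = consensus_logo(aln), amas = amas_conservation(aln),
         z = al2co_standardized(aln)$z)
  }
  fixture <- if (is.character(config$fixture)) {
    read_similarity_fixture(config$fixture)
  } else {
    config$fixture
  }
  per_seq <- lapply(records, function(rec) {
    out <- list(id = rec$id, length = nchar(rec$sequence))
    out$anchors <- map$per_sequence[[rec$id]]
    if (!is.null(config$group_labels)) {
      out$group <- unname(config$group_labels[rec$id])
    }
    if (!is.null(fixture) && rec$id %in% rownames(fixture$matrix$values)) {
      bm <- best_match(fixture$matrix, rec$id)
      out$best_human_match <- bm$reference
      out$best_human_identity <- bm$identity
    }
    topo <- tryCatch(
      withCallingHandlers(
        assign_sidedness(
          predict_tm_segments(rec, window = config$tm_window,
                              threshold = config$tm_threshold,
                              min_len = config$tm_min_len),
          map, rec$id, config$architecture),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) note(rec$id, "topology", e))
    if (!is.null(topo)) {
      out$core_register <- topo$core_register
      out$n_segments <- nrow(topo$segments)
    }
    if (isTRUE(config$run_motifs)) {
      if (!is.null(topo) && nrow(topo$segments) > 0L) {
        out$dileucine <- tryCatch(
          suppressMessages(dileucine_signals(rec, topo)),
          error = function(e) note(rec$id, "dileucine", e))
      }
      out$kxh <- tryCatch(kxh_site(rec, map),
                          error = function(e) note(rec$id, "kxh", e))
      if (!is.null(topo) && !is.null(topo$core_register) &&
          identical(topo$core_register %in% c("TM2-TM5", "TM1-TM4"), TRUE)) {
        out$cysteines <- tryCatch(cysteine_loop_profile(rec, map, topo),
                                  error = function(e) note(rec$id, "cysteines", e))
      }
    }
    if (isTRUE(config$run_checklist)) {
      out$checklist <- tryCatch(ferric_reductase_checklist(rec, map),
                                error = function(e) note(rec$id, "checklist", e))
    }
    out
  })
  names(per_seq) <- vapply(records, `[[`, "", "id")
  summary_df <- do.call(rbind, lapply(per_seq, function(s) {
    data.frame(
      id = s$id, length = s$length,
      group = if (!is.null(s$group)) s$group else NA_character_,
      best_human_match = if (!is.null(s$best_human_match)) s$best_human_match else NA_character_,
      core_register = if (!is.null(s$core_register)) s$core_register else NA_character_,
      n_segments = if (!is.null(s$n_segments)) s$n_segments else NA_integer_,
      n_dileucine = if (!is.null(s$dileucine)) nrow(s$dileucine) else NA_integer_,
      n_kxh = if (!is.null(s$kxh)) nrow(s$kxh) else NA_integer_,
      core4_pass = if (!is.null(s$checklist)) s$checklist$core4_pass else NA,
      stringsAsFactors = FALSE, row.names = NULL)
  }))
  report <- structure(list(
    sequences = per_seq,
    anchors = map,
    conservation = conservation,
    summary = summary_df,
    errors = errors,
    metadata = list(
      package_version = as.character(utils::packageVersion("cytb561anno")),
      schema_version = "1.0",
      n_sequences = length(records),
      parameters = unclass(config)[setdiff(names(config),
                                           c("sequences", "alignment", "fixture"))],
      seed = config$seed)
  ), class = "annotation_report")
  if (!is.null(config$output_dir)) {
    write_report(report, config$output_dir)
  }
  report
}

#' @export
print.annotation_report <- function(x, ...) {
  cat(sprintf("<annotation_report> %d sequence(s), %d error(s)\n",
              x$metadata$n_sequences, length(x$errors)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write a report to disk (JSON summary + per-stage TSVs)
#'
#' @param report An `annotation_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$summary, file.path(dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  anchors_df <- do.call(rbind, lapply(names(report$anchors$per_sequence),
    function(id) {
      idx <- report$anchors$per_sequence[[id]]
      data.frame(accession = id, H1 = idx[1L], H2 = idx[2L], H3 = idx[3L],
                 H4 = idx[4L], stringsAsFactors = FALSE)
    }))
  utils::write.table(anchors_df, file.path(dir, "anchors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(metadata = report$metadata,
         errors = report$errors,
         summary = report$summary),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
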