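# Percent identity over homologous regions, best-human-match classification,
# and a neighbor-joining clustering utility.

#' Construct an identity matrix object
#'
#' @param values Numeric matrix of percent identities in [0, 100] with row
#'   and column names (NA marks a failed/undefined cell).
#' @return Object of class `identity_matrix`.
#' @export
identity_matrix_object <- function(values) {
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("identity matrix needs row and column names")
  }
  rng <- range(values, na.rm = TRUE)
  if (rng[1L] < 0 || rng[2L] > 100) stop("percent identities must lie in [0, 100]")
  structure(list(values = values), class = "identity_matrix")
}

#' @export
print.identity_matrix <- function(x, ...) {
  cat(sprintf("<identity_matrix> %d x %d\n", nrow(x$values), ncol(x$values)))
  print(round(x$values, 1))
  invisible(x)
}

#' Write an identity matrix as TSV (one decimal place)
#' @param mat An `identity_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_identity_matrix <- function(mat, path) {
  df <- data.frame(accession = rownames(mat$values),
                   format(round(mat$values, 1), nsmall = 1, trim = TRUE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Global pairwise alignment with affine gaps
#'
#' End-to-end (Needleman-Wunsch) alignment via
#' [Biostrings::pairwiseAlignment()] under BLOSUM62 with affine gap costs.
#'
#' @param a,b [protein_record()] objects (or plain sequence strings).
#' @param substitution_table Name of the substitution matrix (default
#'   `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return List with gapped `row_a`, `row_b` and the alignment `score`.
#' @export
align_pair <- function(a, b, substitution_table = "BLOSUM62",
                       gap_open = 10, gap_extend = 1) {
  sa <- if (inherits(a, "protein_record")) a$sequence else a
  sb <- if (inherits(b, "protein_record")) b$sequence else b
  if (!nzchar(sa) || !nzchar(sb)) stop("sequences must be non-empty")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sa), Biostrings::AAString(sb),
    substitutionMatrix = substitution_table,
    gapOpening = gap_open, gapExtension = gap_extend, type = "global")
  list(row_a = as.character(Biostrings::pattern(pa)),
       row_b = as.character(Biostrings::subject(pa)),
       score = Biostrings::score(pa))
}

#' Percent identity between two gapped rows
#'
#' Identity = 100 x (columns where both rows carry the identical residue) /
#' (columns where both rows are non-gap). Columns where either row is gapped
#' do not enter the denominator; this convention is symmetric and stable
#' under span restriction. Rounding to one decimal happens only on
#' serialization.
#'
#' @param row_a,row_b Equal-length gapped sequence strings.
#' @return Percent identity, or NA (with a warning) when no column has both
#'   rows non-gap.
#' @export
percent_identity <- function(row_a, row_b) {
  if (nchar(row_a) != nchar(row_b)) stop("rows must have equal length")
  ca <- strsplit(toupper(row_a), "")[[1L]]
  cb <- strsplit(toupper(row_b), "")[[1L]]
  shared <- ca != "-" & cb != "-"
  if (!any(shared)) {
    warning("no columns with both rows non-gap: identity undefined")
    return(NA_real_)
  }
  100 * sum(ca[shared] == cb[shared]) / sum(shared)
}

#' Intersect homologous spans into a common region
#'
#' @param spans List of c(start, end) 1-based inclusive spans on a shared
#'   reference coordinate system.
#' @return c(start, end) of the intersection.
#' @export
common_region <- function(spans) {
  if (length(spans) == 0L) stop("need at least one span")
  starts <- vapply(spans, `[[`, numeric(1L), 1L)
  ends <- vapply(spans, `[[`, numeric(1L), 2L)
  if (any(starts > ends)) stop("malformed span (start > end)")
  out <- c(max(starts), min(ends))
  if (out[1L] > out[2L]) stop("no common region: spans are disjoint")
  as.integer(out)
}

restrict_record <- function(rec, span) {
  s <- if (inherits(rec, "protein_record")) rec$sequence else rec
  if (is.null(span)) return(s)
  if (span[1L] < 1L || span[2L] > nchar(s) || span[1L] > span[2L]) {
    stop(sprintf("span [%d, %d] invalid for sequence of length %d",
                 span[1L], span[2L], nchar(s)))
  }
  substr(s, span[1L], span[2L])
}

#' Pairwise percent-identity matrix
#'
#' Each cell is the percent identity of the global pairwise alignment of the
#' (optionally span-restricted) sequences. Cells whose alignment or identity
#' computation fails are set to NA with a warning rather than aborting the
#' matrix.
#'
#' @param records,refs Lists of [protein_record()]s (rows and columns).
#' @param spans Optional named list of c(start, end) homologous spans,
#'   looked up by record id for rows and columns alike.
#' @param ... Passed to [align_pair()].
#' @return An [identity_matrix_object()].
#' @export
identity_matrix <- function(records, refs, spans = NULL, ...) {
  row_ids <- vapply(records, `[[`, "", "id")
  col_ids <- vapply(refs, `[[`, "", "id")
  vals <- matrix(NA_real_, length(records), length(refs),
                 dimnames = list(row_ids, col_ids))
  for (i in seq_along(records)) {
    si <- restrict_record(records[[i]], spans[[row_ids[i]]])
    for (j in seq_along(refs)) {
      sj <- restrict_record(refs[[j]], spans[[col_ids[j]]])
      vals[i, j] <- tryCatch({
        al <- align_pair(si, sj, ...)
        percent_identity(al$row_a, al$row_b)
      }, error = function(e) {
        warning(sprintf("cell (%s, %s) failed: %s", row_ids[i], col_ids[j],
                        conditionMessage(e)))
        NA_real_
      })
    }
  }
  identity_matrix_object(vals)
}

#' Percent-identity matrix from a precomputed multiple alignment
#'
#' Extracts row pairs from one joint alignment instead of re-aligning
#' pairwise — the protocol used when identities should reflect a specific
#' family MSA.
#'
#' @param aln An [alignment_block()].
#' @param row_ids,col_ids Ids selecting matrix rows and columns.
#' @return An [identity_matrix_object()].
#' @export
identity_matrix_from_alignment <- function(aln, row_ids, col_ids) {
  vals <- matrix(NA_real_, length(row_ids), length(col_ids),
                 dimnames = list(row_ids, col_ids))
  for (i in row_ids) {
    for (j in col_ids) {
      vals[i, j] <- if (identical(i, j)) 100 else {
        percent_identity(aln$rows[[i]], aln$rows[[j]])
      }
    }
  }
  identity_matrix_object(vals)
}

#' Best human match of one row
#'
#' Argmax over columns; ties break to the earliest column in the matrix's
#' fixed column order.
#'
#' @param mat An `identity_matrix`.
#' @param row_id Row accession.
#' @return List with `reference` (column id) and `identity`.
#' @export
best_match <- function(mat, row_id) {
  if (!row_id %in% rownames(mat$values)) {
    stop(sprintf("unknown row: %s", row_id))
  }
  v <- mat$values[row_id, ]
  if (all(is.na(v))) stop(sprintf("row %s has no non-missing cells", row_id))
  k <- which.max(v)  # first maximum = fixed column-order tie-break
  list(reference = colnames(mat$values)[k], identity = unname(v[k]))
}

#' Flag rows more similar to a human reference than to any conspecific model
#'
#' A row is flagged when its maximum over the human-reference columns is
#' strictly greater than its maximum over the D. melanogaster columns
#' (self-comparisons excluded from the latter).
#'
#' @param human_matrix,dm_matrix `identity_matrix` objects sharing row ids.
#' @return Named logical vector per row.
#' @export
flag_group4a <- function(human_matrix, dm_matrix) {
  rows <- rownames(human_matrix$values)
  missing <- setdiff(rows, rownames(dm_matrix$values))
  if (length(missing) > 0L) {
    stop(sprintf("row(s) missing from the D. melanogaster matrix: %s",
                 paste(missing, collapse = ", ")))
  }
  out <- vapply(rows, function(r) {
    hmax <- max(human_matrix$values[r, ], na.rm = TRUE)
    dcols <- setdiff(colnames(dm_matrix$values), r)
    dmax <- max(dm_matrix$values[r, dcols], na.rm = TRUE)
    hmax > dmax
  }, logical(1L))
  stats::setNames(out, rows)
}

#' Per-group best-match summary
#'
#' @param mat An `identity_matrix`.
#' @param group_labels Named character vector, one label per matrix row.
#' @return Object of class `group_summary`: per-row best matches and, per
#'   group, counts of the best-match column plus min/max best identities.
#' @export
summarize_groups <- function(mat, group_labels) {
  rows <- rownames(mat$values)
  missing <- setdiff(rows, names(group_labels))
  if (length(missing) > 0L) {
    stop(sprintf("unlabeled row(s): %s", paste(missing, collapse = ", ")))
  }
  best <- lapply(rows, function(r) best_match(mat, r))
  best_ref <- vapply(best, `[[`, "", "reference")
  best_val <- vapply(best, `[[`, numeric(1L), "identity")
  labels <- group_labels[rows]
  groups <- lapply(split(seq_along(rows), labels), function(idx) {
    list(n = length(idx),
         best_counts = table(factor(best_ref[idx], levels = colnames(mat$values))),
         best_range = c(min = min(best_val[idx]), max = max(best_val[idx])))
  })
  structure(list(best = data.frame(accession = rows, group = unname(labels),
                                   reference = best_ref, identity = best_val,
                                   stringsAsFactors = FALSE),
                 groups = groups),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  for (g in names(x$groups)) {
    s <- x$groups[[g]]
    tops <- s$best_counts[s$best_counts > 0L]
    cat(sprintf("%s (n=%d): best %s; best-identity range %.1f-%.1f\n",
                g, s$n,
                paste(sprintf("%s x%d", names(tops), tops), collapse = ", "),
                s$best_range[1L], s$best_range[2L]))
  }
  invisible(x)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration via [ape::nj()]. Negative branch lengths are
#' clamped to zero with a warning. This is a distance-based clustering
#' utility, not a substitute for model-based phylogenetic inference; the
#' Newick string carries a `[method: NJ]` comment-free label via the return
#' value's `method` attribute instead.
#'
#' @param distances Square symmetric numeric matrix with zero diagonal and
#'   row/column labels (>= 3 taxa).
#' @return Newick text (character scalar) with attribute `method = "NJ"`.
#' @export
nj_tree <- function(distances) {
  if (!is.matrix(distances) || nrow(distances) != ncol(distances)) {
    stop("'distances' must be a square matrix")
  }
  if (nrow(distances) < 3L) stop("need at least 3 taxa")
  if (max(abs(distances - t(distances))) > 1e-8) {
    stop("'distances' must be symmetric")
  }
  if (any(abs(diag(distances)) > 1e-8)) stop("diagonal must be zero")
  if (is.null(rownames(distances))) {
    rownames(distances) <- colnames(distances) <- paste0("t", seq_len(nrow(distances)))
  }
  tree <- ape::nj(stats::as.dist(distances))
  if (any(tree$edge.length < 0)) {
    warning("negative branch length(s) clamped to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  nwk <- ape::write.tree(tree)
  attr(nwk, "method") <- "NJ"
  nwk
}
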