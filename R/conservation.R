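# Alignment-column conservation: consensus symbols, an AMAS-style
# physicochemical property score (0-11), and standardized entropy z-scores.

column_counts <- function(aln) {
  mat <- alignment_matrix(aln)
  apply(mat, 2L, function(col) {
    table(factor(col, levels = c(AA_STANDARD, AA_AMBIGUOUS, "-")))
  })
}

#' Consensus symbols and residue frequencies per column
#'
#' The consensus symbol is the modal residue; `'+'` marks columns where two
#' or more residues tie for the highest frequency, and `'-'` marks columns
#' where the gap frequency strictly exceeds every residue's frequency.
#'
#' @param aln An [alignment_block()].
#' @return Object of class `conservation_profile` with `frequencies`
#'   (residues + gap, columns sum to 1) and `consensus` (one symbol per
#'   column).
#' @export
consensus_logo <- function(aln) {
  counts <- column_counts(aln)
  n <- length(aln$ids)
  freqs <- counts / n
  consensus <- apply(counts, 2L, function(ct) {
    res <- ct[setdiff(names(ct), "-")]
    gap <- ct[["-"]]
    if (gap > max(res)) return("-")
    top <- res[res == max(res)]
    if (length(top) >= 2L) "+" else names(top)
  })
  structure(list(frequencies = freqs, consensus = unname(consensus),
                 n_sequences = n),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat(sprintf("<conservation_profile> %d columns, %d sequences\n",
              length(x$consensus), x$n_sequences))
  cat("consensus:", paste(x$consensus, collapse = ""), "\n")
  invisible(x)
}

amas_score_column <- function(col) {
  residues <- unique(col[col %in% AA_STANDARD])
  has_gap <- any(col == "-")
  if (length(residues) == 0L) return(0L)  # gap-only (or ambiguity-only) column
  if (length(residues) == 1L && !has_gap) return(11L)
  sub <- AA_PROPERTIES[, residues, drop = FALSE]
  agree <- sum(apply(sub, 1L, function(row) all(row) || !any(row)))
  score <- if (has_gap) agree - 1L else agree
  max(score, 0L)
}

#' AMAS-style per-column conservation score (0-11)
#'
#' For each column, the set of distinct standard residues present is scored
#' by the number of the ten Livingstone-Barton physicochemical properties
#' (hydrophobic, polar, small, tiny, aliphatic, aromatic, charged, positive,
#' negative, proline) on which all members agree — every member has the
#' property, or none does. A gap-free single-residue column scores the
#' maximal 11; a column containing any gap loses the identity bonus and one
#' further point (floor 0); a gap-only column scores 0.
#'
#' @param aln An [alignment_block()].
#' @return Integer vector of per-column scores.
#' @export
amas_conservation <- function(aln) {
  mat <- alignment_matrix(aln)
  vapply(seq_len(ncol(mat)), function(j) amas_score_column(mat[, j]), integer(1L))
}

#' Standardized entropy conservation z-scores
#'
#' Column entropy `S = -sum f_a log f_a` over the frequencies of standard
#' residues among non-gap entries (natural log, no sequence weighting). The
#' reported score is `z = (mean(S) - S) / sd(S)`, so higher means more
#' conserved. `z_display` additionally clamps to [-1.5, 1.5], the range used
#' for structure coloring.
#'
#' @param aln An [alignment_block()].
#' @return List with `entropy`, `z`, and `z_display` vectors.
#' @export
al2co_standardized <- function(aln) {
  mat <- alignment_matrix(aln)
  entropy <- vapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    col <- col[col %in% AA_STANDARD]
    if (length(col) == 0L) return(NA_real_)
    f <- table(col) / length(col)
    -sum(f * log(f))
  }, numeric(1L))
  sdS <- stats::sd(entropy, na.rm = TRUE)
  if (is.na(sdS) || sdS == 0) {
    warning("all columns have identical entropy: z-scores undefined, reported as 0")
    z <- ifelse(is.na(entropy), NA_real_, 0)
  } else {
    z <- (mean(entropy, na.rm = TRUE) - entropy) / sdS
  }
  list(entropy = entropy, z = z, z_display = pmin(pmax(z, -1.5), 1.5))
}

#' Per-group conservation profiles
#'
#' Runs [consensus_logo()] and [amas_conservation()] on each group's
#' row-subset alignment; all-gap columns are retained so column indices stay
#' comparable across groups.
#'
#' @param aln An [alignment_block()].
#' @param group_labels Named character vector mapping every row id to a
#'   group label.
#' @return Named list per group, each with `profile` (a
#'   `conservation_profile`) and `amas` scores.
#' @export
group_consensus <- function(aln, group_labels) {
  missing <- setdiff(aln$ids, names(group_labels))
  if (length(missing) > 0L) {
    stop(sprintf("unlabeled row(s): %s", paste(missing, collapse = ", ")))
  }
  groups <- split(aln$ids, group_labels[aln$ids])
  lapply(groups, function(ids) {
    sub <- alignment_block(aln$rows[ids])
    list(profile = consensus_logo(sub), amas = amas_conservation(sub))
  })
}

#' Write a per-column conservation profile as TSV
#'
#' @param aln An [alignment_block()].
#' @param path Output path.
#' @return The profile data frame, invisibly.
#' @export
write_conservation_profile <- function(aln, path) {
  logo <- consensus_logo(aln)
  z <- al2co_standardized(aln)
  df <- data.frame(column = seq_along(logo$consensus),
                   consensus = logo$consensus,
                   amas = amas_conservation(aln),
                   z = round(z$z, 4))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
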