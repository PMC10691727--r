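# Conserved-histidine anchoring and the H1..H4-relative coordinate system.
#
# Cytb561 proteins carry four universally conserved heme-coordinating
# histidines (H1-H4). Once located in a family alignment they define a
# residue coordinate system ("H1+20" = 20 residues downstream of H1) that
# makes positions comparable across diverged sequences.

#' Locate the four conserved histidine anchor columns
#'
#' Candidate columns are those whose histidine fraction (over all rows,
#' gaps counting against) is at least `h_min`. Among all quadruples of
#' candidates whose consecutive spacings fall within `[min_gap, max_gap]`
#' alignment columns, the one maximizing the summed histidine fraction is
#' chosen; ties break to the leftmost column vector.
#'
#' @param aln An [alignment_block()] with at least 2 sequences.
#' @param h_min Minimum per-column histidine fraction (default 0.95; below
#'   1 so a single truncated sequence does not abort anchor detection).
#' @param min_gap,max_gap Allowed consecutive anchor spacing, in columns.
#' @return An object of class `anchor_map`: `anchor_columns` (4 increasing
#'   1-based column indices), `per_sequence` (id -> 4 residue indices in the
#'   ungapped sequence, NA where the row is gapped or non-His at the column),
#'   `his_fraction` per anchor, and `sequences` (ungapped sequences, for
#'   coordinate resolution).
#' @export
find_histidine_anchors <- function(aln, h_min = 0.95, min_gap = 15L,
                                   max_gap = 90L) {
  if (length(aln$ids) < 2L) stop("anchor detection needs >= 2 sequences")
  mat <- alignment_matrix(aln)
  his_frac <- colMeans(mat == "H")
  cand <- which(his_frac >= h_min)
  if (length(cand) < 4L) {
    stop(sprintf(
      "anchors not found: only %d candidate column(s) with His fraction >= %g (at %s)",
      length(cand), h_min,
      if (length(cand)) paste(cand, collapse = ", ") else "none"))
  }
  best <- NULL
  best_score <- -Inf
  quads <- utils::combn(cand, 4L)
  for (j in seq_len(ncol(quads))) {
    q <- quads[, j]
    gaps <- diff(q)
    if (any(gaps < min_gap) || any(gaps > max_gap)) next
    sc <- sum(his_frac[q])
    if (sc > best_score + 1e-12) {
      best <- q
      best_score <- sc
    }
    # ties: combn enumerates in lexicographic order, so the first max wins
  }
  if (is.null(best)) {
    stop(sprintf(
      "anchors not found: no spacing-feasible quadruple among candidates %s (spacing %d-%d)",
      paste(cand, collapse = ", "), min_gap, max_gap))
  }
  per_seq <- lapply(aln$ids, function(id) {
    row <- mat[id, ]
    res_idx <- cumsum(row != "-")
    idx <- ifelse(row[best] == "H", res_idx[best], NA_integer_)
    as.integer(idx)
  })
  names(per_seq) <- aln$ids
  seqs <- vapply(aln$ids, function(id) ungap_row(aln, id), character(1L))
  structure(list(anchor_columns = as.integer(best),
                 per_sequence = per_seq,
                 his_fraction = unname(his_frac[best]),
                 sequences = seqs),
            class = "anchor_map")
}

#' @export
print.anchor_map <- function(x, ...) {
  cat(sprintf("<anchor_map> H1-H4 at columns %s (%d sequences)\n",
              paste(x$anchor_columns, collapse = "/"),
              length(x$per_sequence)))
  invisible(x)
}

# character matrix view of an alignment (rows = ids)
alignment_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$rows, ""))
  rownames(m) <- aln$ids
  m
}

anchor_indices <- function(map, seq_id) {
  if (!seq_id %in% names(map$per_sequence)) {
    stop(sprintf("sequence '%s' is not mapped in the anchor map", seq_id))
  }
  idx <- map$per_sequence[[seq_id]]
  if (anyNA(idx)) {
    stop(sprintf("sequence '%s' has unmapped anchor(s): %s", seq_id,
                 paste(paste0("H", which(is.na(idx))), collapse = ", ")))
  }
  idx
}

#' Histidine-relative position
#'
#' @param anchor Anchor name, `"H1"`..`"H4"`.
#' @param offset Signed integer offset in residues (0 allowed).
#' @return An object of class `relpos`.
#' @examples
#' format(relpos("H1", 20))   # "H1+20"
#' format(relpos("H2", 0))    # "H2"
#' @export
relpos <- function(anchor, offset) {
  anchor <- match.arg(anchor, paste0("H", 1:4))
  structure(list(anchor = anchor, offset = as.integer(offset)), class = "relpos")
}

#' @export
format.relpos <- function(x, ...) {
  if (x$offset == 0L) return(x$anchor)
  sprintf("%s%s%d", x$anchor, if (x$offset > 0L) "+" else "-", abs(x$offset))
}

#' @export
print.relpos <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Parse a histidine-relative label such as "H3-5"
#' @param label Label string (`"H1+20"`, `"H3-5"`, `"H2"`).
#' @return A [relpos()].
#' @export
parse_relpos <- function(label) {
  m <- regmatches(label, regexec("^(H[1-4])(([+-])([0-9]+))?$", label))[[1L]]
  if (length(m) == 0L) stop(sprintf("malformed relative position: '%s'", label))
  off <- if (nzchar(m[3L])) as.integer(m[5L]) * if (m[4L] == "-") -1L else 1L else 0L
  relpos(m[2L], off)
}

#' Express a residue index relative to its labeling anchor
#'
#' The label uses the downstream (`+`) form from the preceding anchor unless
#' the upstream offset to the following anchor is strictly less than half the
#' downstream offset, in which case the upstream (`-`) form is used. This
#' reproduces the field's labeling practice, where positions such as +20/+22
#' are preferred over nearer upstream alternatives (-16/-12) but short
#' upstream offsets (-2..-7) win against much larger downstream ones.
#'
#' @param map An `anchor_map`.
#' @param seq_id Sequence id present in the map.
#' @param residue_index 1-based index into the ungapped sequence.
#' @return A [relpos()].
#' @export
to_relative <- function(map, seq_id, residue_index) {
  anchors <- anchor_indices(map, seq_id)
  n <- nchar(map$sequences[[seq_id]])
  residue_index <- as.integer(residue_index)
  if (residue_index < 1L || residue_index > n) {
    stop(sprintf("residue index %d outside sequence '%s' (length %d)",
                 residue_index, seq_id, n))
  }
  at <- which(anchors == residue_index)
  if (length(at) == 1L) return(relpos(paste0("H", at), 0L))
  prev <- which(anchors < residue_index)
  nxt <- which(anchors > residue_index)
  if (length(prev) == 0L) {
    return(relpos("H1", residue_index - anchors[1L]))
  }
  if (length(nxt) == 0L) {
    return(relpos("H4", residue_index - anchors[4L]))
  }
  k <- max(prev)
  down <- residue_index - anchors[k]        # positive offset from H_k
  up <- anchors[min(nxt)] - residue_index   # magnitude of negative offset
  if (up * 2L < down) {
    relpos(paste0("H", min(nxt)), -up)
  } else {
    relpos(paste0("H", k), down)
  }
}

#' Resolve a histidine-relative position to a residue
#'
#' @param map An `anchor_map`.
#' @param seq_id Sequence id present in the map.
#' @param pos A [relpos()] or label string such as `"H4+25"`.
#' @return List with `index` (1-based residue index) and `residue`
#'   (one-letter code).
#' @export
resolve_relpos <- function(map, seq_id, pos) {
  if (is.character(pos)) pos <- parse_relpos(pos)
  anchors <- anchor_indices(map, seq_id)
  k <- as.integer(substr(pos$anchor, 2L, 2L))
  idx <- anchors[k] + pos$offset
  s <- map$sequences[[seq_id]]
  if (idx < 1L || idx > nchar(s)) {
    stop(sprintf("offset leaves sequence: %s resolves to %d in '%s' (length %d)",
                 format(pos), idx, seq_id, nchar(s)))
  }
  list(index = as.integer(idx), residue = substr(s, idx, idx))
}

#' Core-domain spans around the anchors
#'
#' The core region spans from `upstream_flank` columns before the H1 column
#' to `downstream_flank` columns after the H4 column, clipped to the
#' alignment; per-sequence spans are the ungapped projections (first and last
#' non-gap positions inside the column window).
#'
#' @param map An `anchor_map`.
#' @param aln The [alignment_block()] the map was built from.
#' @param upstream_flank,downstream_flank Flank widths in columns.
#' @return List with `columns` (c(start, end) in alignment columns) and
#'   `spans`: per-sequence c(start, end) residue indices (NA if the sequence
#'   is fully gapped inside the window).
#' @export
core_region <- function(map, aln, upstream_flank = 10L, downstream_flank = 10L) {
  cols <- c(max(1L, map$anchor_columns[1L] - as.integer(upstream_flank)),
            min(aln$n_columns, map$anchor_columns[4L] + as.integer(downstream_flank)))
  mat <- alignment_matrix(aln)
  spans <- lapply(aln$ids, function(id) {
    row <- mat[id, ]
    res_idx <- cumsum(row != "-")
    inside <- which(row != "-" & seq_along(row) >= cols[1L] & seq_along(row) <= cols[2L])
    if (length(inside) == 0L) return(c(NA_integer_, NA_integer_))
    c(res_idx[inside[1L]], res_idx[inside[length(inside)]])
  })
  names(spans) <- aln$ids
  list(columns = cols, spans = spans)
}
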