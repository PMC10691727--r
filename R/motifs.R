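# Region-constrained motif scanning: the KXXXXKXH non-cytoplasmic loop
# motif, C-terminal dileucine sorting signals, the DOMON SXDXXMGXD
# aspartate/methionine pocket, and cysteine-loop profiling.

#' Define a sequence motif
#'
#' Pattern syntax: fixed residues (`K`), the wildcard `X` (any of the 20
#' standard residues), and residue classes written `(D/E)`. Ambiguity codes
#' in a *sequence* (X/B/Z/U) match only wildcard pattern positions, so
#' unknown residues can never satisfy a literal constraint.
#'
#' @param name Motif name.
#' @param pattern Pattern string, e.g. `"KXXXXKXH"` or `"(D/E)XXXL(L/I)"`.
#' @return Object of class `motif_spec` (name, pattern string, and a list of
#'   per-position allowed-residue vectors, NULL meaning wildcard).
#' @export
motif_spec <- function(name, pattern) {
  positions <- list()
  rest <- pattern
  while (nzchar(rest)) {
    if (startsWith(rest, "(")) {
      close <- regexpr(")", rest, fixed = TRUE)
      if (close < 0L) stop(sprintf("unbalanced '(' in pattern '%s'", pattern))
      cls <- strsplit(substr(rest, 2L, close - 1L), "/", fixed = TRUE)[[1L]]
      if (length(cls) == 0L || !all(cls %in% AA_STANDARD)) {
        stop(sprintf("bad residue class in pattern '%s'", pattern))
      }
      positions[[length(positions) + 1L]] <- cls
      rest <- substr(rest, close + 1L, nchar(rest))
    } else {
      ch <- substr(rest, 1L, 1L)
      if (ch == "X") {
        positions[length(positions) + 1L] <- list(NULL)
      } else if (ch %in% AA_STANDARD) {
        positions[[length(positions) + 1L]] <- ch
      } else {
        stop(sprintf("illegal pattern character '%s' in '%s'", ch, pattern))
      }
      rest <- substr(rest, 2L, nchar(rest))
    }
  }
  if (length(positions) < 3L) stop("pattern length must be >= 3")
  structure(list(name = name, pattern = pattern, positions = positions),
            class = "motif_spec")
}

#' @export
print.motif_spec <- function(x, ...) {
  cat(sprintf("<motif_spec> %s: %s (%d positions)\n", x$name, x$pattern,
              length(x$positions)))
  invisible(x)
}

motif_matches_at <- function(chars, start, positions) {
  for (k in seq_along(positions)) {
    ch <- chars[start + k - 1L]
    allowed <- positions[[k]]
    if (is.null(allowed)) {
      if (!(ch %in% c(AA_STANDARD, AA_AMBIGUOUS))) return(FALSE)
    } else {
      if (!(ch %in% allowed)) return(FALSE)
    }
  }
  TRUE
}

#' Scan a sequence for a motif
#'
#' Reports all (possibly overlapping) matches, left to right, optionally
#' restricted to a region.
#'
#' @param seq A [protein_record()] or sequence string.
#' @param spec A [motif_spec()].
#' @param region Optional c(start, end) 1-based residue span; matches must
#'   lie entirely inside it.
#' @param region_label Label recorded on each hit (default `"full"` or
#'   `"region"`).
#' @return Data frame of hits: motif, seq_id, start, end, match, region.
#' @export
scan_motif <- function(seq, spec, region = NULL, region_label = NULL) {
  s <- if (inherits(seq, "protein_record")) seq$sequence else seq
  id <- if (inherits(seq, "protein_record")) seq$id else ""
  chars <- strsplit(s, "")[[1L]]
  k <- length(spec$positions)
  if (is.null(region)) {
    region <- c(1L, length(chars))
    if (is.null(region_label)) region_label <- "full"
  } else {
    region <- as.integer(region)
    if (region[1L] < 1L || region[2L] > length(chars) || region[1L] > region[2L]) {
      stop(sprintf("region [%d, %d] invalid for sequence of length %d",
                   region[1L], region[2L], length(chars)))
    }
    if (is.null(region_label)) region_label <- "region"
  }
  starts <- integer(0L)
  if (region[2L] - region[1L] + 1L >= k) {
    for (i in region[1L]:(region[2L] - k + 1L)) {
      if (motif_matches_at(chars, i, spec$positions)) starts <- c(starts, i)
    }
  }
  data.frame(
    motif = rep(spec$name, length(starts)),
    seq_id = rep(id, length(starts)),
    start = starts, end = starts + k - 1L,
    match = if (length(starts)) substring(s, starts, starts + k - 1L) else character(0L),
    region = rep(region_label, length(starts)),
    stringsAsFactors = FALSE
  )
}

# the package's named motif vocabulary
#' Built-in motif definitions
#'
#' `"KXXXXKXH"` (non-cytoplasmic loop, TScytb-like), `"EDXXLL"` (exact
#' dileucine signal of CG1275-type tails), `"(D/E)XXXL(L/I)"`
#' (late-endosomal/lysosomal dileucine signal), `"DXXLL"` (trans-Golgi
#' sorting signal), `"SXDXXMGXD"` (DOMON aspartate/methionine pocket).
#'
#' @param name One of the built-in motif names.
#' @return A [motif_spec()].
#' @export
builtin_motif <- function(name = c("KXXXXKXH", "EDXXLL", "(D/E)XXXL(L/I)",
                                   "DXXLL", "SXDXXMGXD")) {
  name <- match.arg(name)
  motif_spec(name, name)
}

#' C-terminal dileucine sorting signals
#'
#' Scans only the tail downstream of the last transmembrane segment for
#' three signal patterns; each hit is labeled with the most specific pattern
#' it satisfies (EDXXLL > (D/E)XXXL(L/I); DXXLL is reported separately as it
#' has different length).
#'
#' @param seq A [protein_record()].
#' @param topology A `tm_topology` with at least one segment.
#' @return Data frame of hits (possibly empty; empty with a message when the
#'   last segment runs to the C-terminus).
#' @export
dileucine_signals <- function(seq, topology) {
  if (nrow(topology$segments) == 0L) stop("topology has no segments")
  s <- if (inherits(seq, "protein_record")) seq$sequence else seq
  tail_start <- topology$segments[nrow(topology$segments), 2L] + 1L
  empty <- scan_motif(seq, builtin_motif("EDXXLL"), c(1L, 3L))[0L, ]
  if (tail_start > nchar(s)) {
    message("no C-terminal tail downstream of the last TM segment")
    return(empty)
  }
  region <- c(tail_start, nchar(s))
  hits6 <- scan_motif(seq, builtin_motif("(D/E)XXXL(L/I)"), region, "C-terminal tail")
  if (nrow(hits6) > 0L) {
    exact <- scan_motif(seq, builtin_motif("EDXXLL"), region, "C-terminal tail")
    hits6$motif[hits6$start %in% exact$start] <- "EDXXLL"
  }
  hits5 <- scan_motif(seq, builtin_motif("DXXLL"), region, "C-terminal tail")
  out <- rbind(hits6, hits5)
  out[order(out$start, out$motif), , drop = FALSE]
}

#' KXXXXKXH site in the H2-H3 non-cytoplasmic window
#'
#' Scans the inter-anchor window (H2+1 .. H3-1, sequence coordinates) for
#' the KXXXXKXH motif and reports whether the matched histidine sits exactly
#' at H3-5 — the canonical register, which implies the two lysines at H3-12
#' and H3-7.
#'
#' @param seq A [protein_record()].
#' @param map An `anchor_map` covering the sequence.
#' @return Data frame of hits with an extra `canonical_register` column.
#' @export
kxh_site <- function(seq, map) {
  id <- if (inherits(seq, "protein_record")) seq$id else ""
  anchors <- anchor_indices(map, id)
  region <- c(anchors[2L] + 1L, anchors[3L] - 1L)
  hits <- scan_motif(seq, builtin_motif("KXXXXKXH"), region,
                     "non-cytoplasmic loop (H2..H3)")
  hits$canonical_register <- hits$end == anchors[3L] - 5L
  hits
}

#' DOMON heme-ligand detection
#'
#' The putative heme-ligating methionine is the M of the unique SXDXXMGXD
#' match inside the DOMON span (NA if absent or ambiguous). The partner
#' histidine requires an alignment of DOMON domains: it is this sequence's
#' residue at the first alignment column downstream of the Met column that
#' carries His in at least 90% of rows; in single-sequence mode His is NA.
#'
#' @param seq A [protein_record()].
#' @param domon_span c(start, end) residue span of the DOMON domain.
#' @param aln Optional [alignment_block()] of DOMON domains including this
#'   sequence.
#' @param his_min Minimum His column fraction (default 0.9).
#' @return List with `met_index` and `his_index` (1-based, NA when not
#'   determined).
#' @export
domon_heme_ligands <- function(seq, domon_span, aln = NULL, his_min = 0.9) {
  s <- if (inherits(seq, "protein_record")) seq$sequence else seq
  id <- if (inherits(seq, "protein_record")) seq$id else ""
  hits <- scan_motif(seq, builtin_motif("SXDXXMGXD"), as.integer(domon_span),
                     "DOMON")
  if (nrow(hits) != 1L) {
    return(list(met_index = NA_integer_, his_index = NA_integer_))
  }
  met <- hits$start[1L] + 5L
  if (is.null(aln)) {
    message("no DOMON alignment supplied: partner histidine not determined")
    return(list(met_index = met, his_index = NA_integer_))
  }
  if (!id %in% aln$ids) stop(sprintf("sequence '%s' not in DOMON alignment", id))
  mat <- alignment_matrix(aln)
  row <- mat[id, ]
  res_idx <- cumsum(row != "-")
  met_col <- which(res_idx == met & row != "-")[1L]
  if (is.na(met_col)) return(list(met_index = met, his_index = NA_integer_))
  his_frac <- colMeans(mat == "H")
  cand <- which(seq_along(his_frac) > met_col & his_frac >= his_min)
  cand <- cand[row[cand] != "-"]
  if (length(cand) == 0L) {
    return(list(met_index = met, his_index = NA_integer_))
  }
  list(met_index = met, his_index = unname(res_idx[cand[1L]]))
}

#' Cysteine profile of the three core-domain loops
#'
#' Counts cysteines and flags CC doublets in each of the three core loops
#' (cytoplasmic / non-cytoplasmic / cytoplasmic). A sequence is
#' "Nemy-like cysteine-rich" when both cytoplasmic loops carry >= 2 Cys.
#'
#' @param seq A [protein_record()].
#' @param map An `anchor_map`.
#' @param topology A completed `tm_topology` (register determined).
#' @return List with per-loop `cys_count`, `double_cys`, loop `sides`, and
#'   the overall `nemy_like` flag.
#' @export
cysteine_loop_profile <- function(seq, map, topology) {
  id <- if (inherits(seq, "protein_record")) seq$id else ""
  s <- if (inherits(seq, "protein_record")) seq$sequence else seq
  loops <- core_loops(topology, map, id)
  sides <- attr(loops, "sides")
  counts <- integer(3L)
  doubles <- logical(3L)
  for (j in 1:3) {
    span <- loops[[j]]
    frag <- if (span[1L] > span[2L]) "" else substr(s, span[1L], span[2L])
    counts[j] <- lengths(regmatches(frag, gregexpr("C", frag)))
    doubles[j] <- grepl("CC", frag, fixed = TRUE)
  }
  cyto <- sides == "cytoplasmic"
  list(cys_count = counts, double_cys = doubles, sides = sides,
       nemy_like = all(counts[cyto] >= 2L))
}
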