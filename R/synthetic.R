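# Seeded generator of cytb561-like protein families with full ground truth:
# six hydrophobic transmembrane segments, four planted histidine anchors,
# group-specific conserved sites at histidine-relative offsets, optional
# planted motifs with per-sequence on/off truth, and loop-restricted indels.
# Every emitted feature is recorded, so recovery by the annotation stages is
# directly assertable.

TM_POOL <- c("L", "I", "V", "F")
LOOP_POOL <- c("D", "E", "N", "Q", "S", "T", "G", "P", "R", "K")
# scaffold loops lean strongly hydrophilic so helix/loop contrast survives
# the polar functional residues planted inside helices
LOOP_POOL_W <- c(D = 2, E = 2, N = 2, Q = 2, S = 1, T = 1, G = 1, P = 1,
                 R = 2, K = 2) / 16
TM_LEN <- 21L
ANCHOR_TM_OFFSET <- 4L  # anchors sit at the 4th residue of their helix

#' Family simulation specification
#'
#' Defaults mirror the study family this generator emulates: five groups
#' (11 CG1275-like and 8 Nemy-like single-domain sequences, 10 CYBDOM-class
#' CG8399-like sequences, 7 Group-4A-like and 18 Group-4B-like sequences),
#' inter-anchor spacings 36/34/39 (the register of duodenal cytochrome b561,
#' whose anchors fall at residues 50/86/120/159 under the default layout),
#' the ferric-reductase residue catalog planted in the Dcytb-like groups,
#' group-diagnostic motifs (C-terminal EDXXLL in CG1275-like tails, the
#' KXXXXKXH loop motif in 6/7 of Group-4A-like sequences, the DOMON
#' SXDXXMGXD pocket in CG8399-like N-terminal regions), double cysteines in
#' the Nemy-like cytoplasmic loops, a 20% per-site substitution rate at
#' unconstrained sites and a 10% per-loop indel rate.
#'
#' @param groups Data frame with columns label, n, architecture
#'   ("single-domain" or "cybdom").
#' @param anchor_offsets Three inter-anchor spacings in residues.
#' @param conserved_sites List of `list(pos, residues, groups)` entries
#'   (`groups = NULL` means all groups); the first residue of each class is
#'   written into the template.
#' @param planted_motifs List of `list(name, region, groups, prob)` entries;
#'   region is one of "H2H3_loop", "tail", "nterm".
#' @param site_mutation_rate Per-site substitution probability at
#'   unconstrained sites.
#' @param loop_indel_rate Per-loop insertion/deletion probability.
#' @param seed Integer seed; identical (spec, seed) give identical output.
#' @return Object of class `family_spec`.
#' @export
family_spec <- function(groups = default_groups(),
                        anchor_offsets = c(36L, 34L, 39L),
                        conserved_sites = default_conserved_sites(),
                        planted_motifs = default_planted_motifs(),
                        site_mutation_rate = 0.2,
                        loop_indel_rate = 0.1,
                        seed = 1L) {
  if (length(anchor_offsets) != 3L || any(anchor_offsets < 31L) ||
      any(anchor_offsets > 53L)) {
    stop("anchor_offsets must be 3 spacings in [31, 53] residues")
  }
  if (site_mutation_rate < 0 || site_mutation_rate > 1 ||
      loop_indel_rate < 0 || loop_indel_rate > 1) {
    stop("rates must lie in [0, 1]")
  }
  structure(list(groups = groups, anchor_offsets = as.integer(anchor_offsets),
                 conserved_sites = conserved_sites,
                 planted_motifs = planted_motifs,
                 site_mutation_rate = site_mutation_rate,
                 loop_indel_rate = loop_indel_rate,
                 seed = as.integer(seed)),
            class = "family_spec")
}

#' @rdname family_spec
#' @export
default_groups <- function() {
  data.frame(
    label = c("CG1275", "Nemy", "CG8399", "Group 4A", "Group 4B"),
    n = c(11L, 8L, 10L, 7L, 18L),
    architecture = c("single-domain", "single-domain", "cybdom",
                     "single-domain", "single-domain"),
    stringsAsFactors = FALSE
  )
}

dcytb_like_groups <- c("CG1275", "Nemy")

#' @rdname family_spec
#' @export
default_conserved_sites <- function() {
  site <- function(pos, residues, groups = NULL) {
    list(pos = pos, residues = residues, groups = groups)
  }
  c(
    # Dcytb-derived substrate/heme catalog in the Dcytb-like groups
    lapply(list(
      c("H2+22", "H"), c("H2+21", "N"), c("H3-3", "Y"), c("H4+25", "F"),
      c("H1-3", "F"), c("H2-7", "K"), c("H2-3", "K"), c("H4-7", "R"),
      c("H1+20", "R"), c("H3+14", "Q"), c("H3-2", "S"), c("H3-5", "N"),
      c("H3+2", "W"), c("H3-4", "M"), c("H4+21", "E")
    ), function(p) site(p[1L], p[2L], dcytb_like_groups)),
    list(
      # small heme-packing residues, family-wide
      site("H3+4", "G"), site("H4+4", "G"),
      site("H3+18", "G", c("CG1275", "Nemy", "Group 4A", "Group 4B")),
      site("H4+18", "G", c("CG1275", "Nemy", "Group 4A", "Group 4B")),
      site("H3+18", "A", "CG8399"), site("H4+18", "A", "CG8399"),
      # CYBDOM-class cytb561 domain: nonpolar H2+22, glutamate H2+21,
      # asparagine at H3-2, conserved basics
      site("H2+22", "L", "CG8399"), site("H2+21", "E", "CG8399"),
      site("H3-2", "N", "CG8399"), site("H1+20", "R", "CG8399"),
      site("H3+14", "Q", "CG8399"), site("H4-7", "R", "CG8399"),
      # Group 4: polar H1+20/H3+14, lysine H2+22, histidine H3-5
      site("H1+20", "S", c("Group 4A", "Group 4B")),
      site("H3+14", "S", c("Group 4A", "Group 4B")),
      site("H2+22", "K", "Group 4B"),
      site("H3-5", "H", c("Group 4A", "Group 4B")),
      site("H1-3", "F", "Group 4A"),
      # Nemy-diagnostic double cysteines in both cytoplasmic core loops
      site("H2-11", "C", "Nemy"), site("H2-10", "C", "Nemy"),
      site("H4-12", "C", "Nemy"), site("H4-11", "C", "Nemy")
    )
  )
}

#' @rdname family_spec
#' @export
default_planted_motifs <- function() {
  list(
    list(name = "EDXXLL", region = "tail", groups = "CG1275", prob = 1),
    # the study condition: the motif is present in exactly 6 of the 7
    # TScytb-like sequences
    list(name = "KXXXXKXH", region = "H2H3_loop", groups = "Group 4A",
         count = 6L),
    list(name = "SXDXXMGXD", region = "nterm", groups = "CG8399", prob = 1)
  )
}

template_layout <- function(spec, architecture) {
  off <- spec$anchor_offsets
  loops_between_anchor_tms <- off - TM_LEN  # must be plausible loop lengths
  if (any(loops_between_anchor_tms < 8L) || any(loops_between_anchor_tms > 30L)) {
    stop("anchor offsets imply loop lengths outside 8-30")
  }
  if (architecture == "single-domain") {
    # default offsets 36/34/39 place the anchors at residues 50/86/120/159,
    # the register of duodenal cytochrome b561
    seg_lens <- c(nterm = 7L, TM1 = TM_LEN, loop1 = 18L, TM2 = TM_LEN,
                  loop2 = loops_between_anchor_tms[1L], TM3 = TM_LEN,
                  loop3 = loops_between_anchor_tms[2L], TM4 = TM_LEN,
                  loop4 = loops_between_anchor_tms[3L], TM5 = TM_LEN,
                  loop5 = 18L, TM6 = TM_LEN, tail = 20L)
    anchor_tms <- c("TM2", "TM3", "TM4", "TM5")
  } else {
    seg_lens <- c(nterm = 47L, TM1 = TM_LEN,
                  loop1 = loops_between_anchor_tms[1L], TM2 = TM_LEN,
                  loop2 = loops_between_anchor_tms[2L], TM3 = TM_LEN,
                  loop3 = loops_between_anchor_tms[3L], TM4 = TM_LEN,
                  loop4 = 18L, TM5 = TM_LEN, loop5 = 18L, TM6 = TM_LEN,
                  tail = 20L)
    anchor_tms <- c("TM1", "TM2", "TM3", "TM4")
  }
  ends <- cumsum(seg_lens)
  starts <- ends - seg_lens + 1L
  spans <- cbind(start = starts, end = ends)
  rownames(spans) <- names(seg_lens)
  anchors <- spans[anchor_tms, "start"] + ANCHOR_TM_OFFSET - 1L
  list(spans = spans, anchors = unname(anchors),
       tm_spans = spans[grep("^TM", rownames(spans)), , drop = FALSE],
       loop_spans = spans[grep("^(loop|nterm|tail)", rownames(spans)), ,
                          drop = FALSE])
}

resolve_offset <- function(anchors, pos) {
  rp <- parse_relpos(pos)
  k <- as.integer(substr(rp$anchor, 2L, 2L))
  anchors[k] + rp$offset
}

#' Build a family template with planted anchors and conserved sites
#'
#' The template has six strongly hydrophobic helices (Kyte-Doolittle mean
#' well above 2) separated by hydrophilic loops, histidines planted at the
#' four anchor positions of the architecture-appropriate helices, and each
#' conserved site written at its resolved offset.
#'
#' @param spec A [family_spec()].
#' @param architecture `"single-domain"` or `"cybdom"`.
#' @return List with `record` (a [protein_record()]), and `truth`: anchors,
#'   TM segment spans, loop spans, per-position constraint mask, layout.
#' @export
make_template <- function(spec, architecture = c("single-domain", "cybdom")) {
  architecture <- match.arg(architecture)
  lay <- template_layout(spec, architecture)
  n <- max(lay$spans[, "end"])
  chars <- character(n)
  for (seg in rownames(lay$spans)) {
    span <- lay$spans[seg, ]
    n_seg <- span[2L] - span[1L] + 1L
    chars[span[1L]:span[2L]] <- if (grepl("^TM", seg)) {
      sample(TM_POOL, n_seg, replace = TRUE)
    } else {
      sample(LOOP_POOL, n_seg, replace = TRUE, prob = LOOP_POOL_W)
    }
  }
  chars[lay$anchors] <- "H"
  constrained <- logical(n)
  constrained[lay$anchors] <- TRUE
  arch_groups <- spec$groups$label[spec$groups$architecture == architecture]
  applicable <- Filter(function(s) {
    is.null(s$groups) || length(intersect(s$groups, arch_groups)) > 0L
  }, spec$conserved_sites)
  sites <- list()
  for (s in applicable) {
    p <- resolve_offset(lay$anchors, s$pos)
    if (p < 1L || p > n) stop(sprintf("conserved site %s resolves outside template", s$pos))
    if (p %in% lay$anchors && s$residues[1L] != "H") {
      stop(sprintf("conserved site %s collides with an anchor", s$pos))
    }
    for (prior in sites) {
      if (prior$position != p) next
      overlap_groups <- intersect(
        if (is.null(prior$groups)) spec$groups$label else prior$groups,
        if (is.null(s$groups)) spec$groups$label else s$groups)
      if (length(overlap_groups) > 0L && !identical(prior$residues, s$residues)) {
        stop(sprintf("conserved sites collide at position %d (%s vs %s)",
                     p, prior$pos, s$pos))
      }
    }
    sites[[length(sites) + 1L]] <- c(s, list(position = p))
    # only residues shared by every group of this architecture belong in the
    # ancestor; group-specific residues are written per group when evolving
    if (is.null(s$groups) || length(setdiff(arch_groups, s$groups)) == 0L) {
      chars[p] <- s$residues[1L]
    }
  }
  record <- protein_record(paste0("template_", architecture),
                           paste(chars, collapse = ""),
                           sprintf("synthetic %s cytb561-like template", architecture))
  truth <- list(architecture = architecture, anchors = lay$anchors,
                tm_spans = lay$tm_spans, loop_spans = lay$loop_spans,
                layout = lay, sites = sites,
                anchor_constrained = constrained)
  list(record = record, truth = truth)
}

fill_motif_instance <- function(name) {
  r <- function(k) sample(setdiff(LOOP_POOL, c("K", "H")), k, replace = TRUE)
  switch(name,
    "KXXXXKXH" = paste(c("K", r(4L), "K", r(1L), "H"), collapse = ""),
    "EDXXLL" = paste(c("E", "D", r(2L), "L", "L"), collapse = ""),
    "SXDXXMGXD" = paste(c("S", r(1L), "D", r(2L), "M", "G", r(1L), "D"),
                        collapse = ""),
    stop(sprintf("no instance filler for motif '%s'", name)))
}

motif_anchor_span <- function(name, region, truth) {
  anchors <- truth$anchors
  len <- nchar(gsub("\\(.*?\\)", "Z", name))  # class groups count 1
  switch(region,
    "H2H3_loop" = {
      # canonical register: motif H at H3-5
      end <- anchors[3L] - 5L
      c(end - len + 1L, end)
    },
    "tail" = {
      # deep enough into the tail that helix-window effects cannot reach it
      span <- truth$layout$spans["tail", ]
      c(span[1L] + 9L, span[1L] + 9L + len - 1L)
    },
    "nterm" = {
      span <- truth$layout$spans["nterm", ]
      c(span[1L] + 19L, span[1L] + 19L + len - 1L)
    },
    stop(sprintf("unknown motif region '%s'", region)))
}

#' Evolve a family group from a template
#'
#' Per sequence: planted motifs are written with their per-sequence
#' probability (or in exactly `count` sequences of the group when the motif
#' entry carries a `count`); when a motif is off, one of its literal
#' positions is spoiled so the motif is genuinely absent at its register and
#' the on/off ground truth is exact. Every unconstrained site is then
#' substituted with probability `site_mutation_rate` (uniform over the other
#' 19 residues), and loops receive insertions/deletions of length 1-5 with
#' probability `loop_indel_rate` each, never touching helices, anchors,
#' conserved sites or planted motifs. Truth coordinates are post-indel.
#'
#' @param template,truth Output of [make_template()].
#' @param spec A [family_spec()].
#' @param group Group label (must exist in `spec$groups`).
#' @param ids Sequence ids to generate (length = group size).
#' @return List with `records`, per-sequence `truth`, and `rows` (gapped
#'   rows of the ground-truth alignment in template coordinates).
#' @export
evolve_family <- function(template, truth, spec, group, ids) {
  if (!inherits(template, "protein_record")) template <- template$record
  tchars <- strsplit(template$sequence, "")[[1L]]
  n <- length(tchars)
  group_sites <- Filter(function(s) is.null(s$groups) || group %in% s$groups,
                        truth$sites)
  site_pos <- vapply(group_sites, `[[`, integer(1L), "position")
  site_res <- vapply(group_sites, function(s) s$residues[1L], character(1L))
  motifs <- Filter(function(m) group %in% m$groups, spec$planted_motifs)
  # per-motif on/off draws for the whole group (exact count or Bernoulli)
  planted_mat <- vapply(motifs, function(m) {
    if (!is.null(m$count)) {
      on <- rep(FALSE, length(ids))
      on[sample(length(ids), min(m$count, length(ids)))] <- TRUE
      on
    } else {
      stats::runif(length(ids)) < m$prob
    }
  }, logical(length(ids)))
  planted_mat <- matrix(planted_mat, nrow = length(ids))

  out_records <- vector("list", length(ids))
  out_truth <- vector("list", length(ids))
  pieces_all <- vector("list", length(ids))

  for (i in seq_along(ids)) {
    chars <- tchars
    # group-specific conserved residues
    chars[site_pos] <- site_res
    constrained <- logical(n)
    constrained[truth$anchors] <- TRUE
    constrained[site_pos] <- TRUE
    motif_truth <- list()
    for (mi in seq_along(motifs)) {
      m <- motifs[[mi]]
      span <- motif_anchor_span(m$name, m$region, truth)
      planted <- planted_mat[i, mi]
      if (planted) {
        inst <- fill_motif_instance(m$name)
        chars[span[1L]:span[2L]] <- strsplit(inst, "")[[1L]]
        constrained[span[1L]:span[2L]] <- TRUE
      } else {
        # spoil one literal position (not a conserved site) so the motif is
        # provably absent at its register
        positions <- motif_spec(m$name, m$name)$positions
        for (k in seq_along(positions)) {
          allowed <- positions[[k]]
          p <- span[1L] + k - 1L
          if (!is.null(allowed) && !(p %in% site_pos)) {
            repl <- setdiff(LOOP_POOL, c(allowed, "H", "K"))
            chars[p] <- sample(repl, 1L)
            constrained[p] <- TRUE
            break
          }
        }
      }
      motif_truth[[length(motif_truth) + 1L]] <-
        list(name = m$name, region = m$region, template_span = span,
             planted = planted)
    }
    # point substitutions at unconstrained sites
    mut_idx <- which(!constrained & stats::runif(n) < spec$site_mutation_rate)
    for (p in mut_idx) {
      chars[p] <- sample(setdiff(AA_STANDARD, chars[p]), 1L)
    }
    # loop indels: pieces[p] is the emitted string for template position p.
    # Indels never fall between an anchor and a feature whose coordinate is
    # anchored to it (conserved-site offsets, the loop-motif register), so
    # histidine-relative positions of planted features survive exactly.
    protected <- constrained
    for (s in group_sites) {
      k <- as.integer(substr(parse_relpos(s$pos)$anchor, 2L, 2L))
      rng <- range(truth$anchors[k], s$position)
      protected[rng[1L]:rng[2L]] <- TRUE
    }
    for (mt in motif_truth) {
      if (!mt$planted || mt$region != "H2H3_loop") next
      rng <- range(mt$template_span, truth$anchors[3L])
      protected[rng[1L]:rng[2L]] <- TRUE
    }
    pieces <- chars
    for (loop in rownames(truth$loop_spans)) {
      if (stats::runif(1L) >= spec$loop_indel_rate) next
      span <- truth$loop_spans[loop, ]
      free <- setdiff(span[1L]:span[2L], which(protected))
      if (length(free) < 6L) next
      len <- sample(5L, 1L)
      if (stats::runif(1L) < 0.5) {  # insertion after a free position
        at <- free[sample(length(free), 1L)]
        pieces[at] <- paste0(pieces[at],
                             paste(sample(LOOP_POOL, len, replace = TRUE),
                                   collapse = ""))
      } else {                        # deletion of a run of free positions
        runs <- runs_from_positions(free)
        run <- runs[[sample(length(runs), 1L)]]
        avail <- run[2L] - run[1L] + 1L
        len <- min(len, avail - 1L)
        if (len < 1L) next
        start <- run[1L] + sample(avail - len + 1L, 1L) - 1L
        pieces[start:(start + len - 1L)] <- ""
      }
    }
    seq_str <- paste(pieces, collapse = "")
    # template position -> residue index in the emitted sequence
    piece_n <- nchar(pieces)
    idx_of <- cumsum(piece_n) - piece_n + 1L  # index of position p's own char
    map_pos <- function(p) if (piece_n[p] == 0L) NA_integer_ else idx_of[p]
    anchors_idx <- vapply(truth$anchors, map_pos, integer(1L))
    tm_spans <- truth$tm_spans
    tm_idx <- cbind(start = vapply(tm_spans[, 1L], map_pos, integer(1L)),
                    end = vapply(tm_spans[, 2L], map_pos, integer(1L)))
    rownames(tm_idx) <- rownames(tm_spans)
    motif_idx <- lapply(motif_truth, function(mt) {
      if (mt$planted) {
        mt$span <- c(map_pos(mt$template_span[1L]), map_pos(mt$template_span[2L]))
      } else {
        mt$span <- c(NA_integer_, NA_integer_)
      }
      mt
    })
    out_records[[i]] <- protein_record(ids[i], seq_str,
                                       sprintf("synthetic %s-like sequence", group))
    out_truth[[i]] <- list(id = ids[i], group = group,
                           architecture = truth$architecture,
                           anchors = anchors_idx, tm_segments = tm_idx,
                           motifs = motif_idx,
                           mutated_template_positions = mut_idx)
    pieces_all[[i]] <- pieces
  }
  names(out_truth) <- ids
  list(records = out_records, truth = out_truth,
       pieces = stats::setNames(pieces_all, ids))
}

# Build the ground-truth alignment (template coordinates; insertions are
# left-aligned extra columns) from per-sequence emitted pieces.
pieces_to_alignment <- function(pieces_all, template_length) {
  width <- integer(template_length)
  for (pieces in pieces_all) {
    w <- nchar(pieces)
    width <- pmax(width, pmax(w, 1L))
  }
  rows <- vapply(pieces_all, function(pieces) {
    padded <- vapply(seq_len(template_length), function(p) {
      s <- pieces[p]
      paste0(s, strrep("-", width[p] - nchar(s)))
    }, character(1L))
    paste(padded, collapse = "")
  }, character(1L))
  anchor_col <- function(template_pos) {
    if (template_pos <= 1L) return(1L)
    sum(width[seq_len(template_pos - 1L)]) + 1L
  }
  list(rows = rows, column_of = anchor_col)
}

#' Simulate a complete cytb561-like family
#'
#' Orchestrates [make_template()] and [evolve_family()] over all groups of
#' the spec and assembles the ground-truth alignment (one alignment per
#' architecture, since the two architectures are not homologous outside the
#' core in this generator).
#'
#' @param spec A [family_spec()].
#' @return List of class `synthetic_family`: `records` (all sequences),
#'   `truth` (per-sequence ground truth), `alignments` (named by
#'   architecture, each an [alignment_block()]), `anchor_columns` (per
#'   architecture, the 4 planted anchor columns), `templates`, and `spec`.
#' @export
simulate_family <- function(spec = family_spec()) {
  set.seed(spec$seed)
  architectures <- unique(spec$groups$architecture)
  templates <- lapply(architectures, function(arch) make_template(spec, arch))
  names(templates) <- architectures
  records <- list()
  truth <- list()
  pieces_by_arch <- stats::setNames(vector("list", length(architectures)),
                                    architectures)
  for (g in seq_len(nrow(spec$groups))) {
    label <- spec$groups$label[g]
    arch <- spec$groups$architecture[g]
    ids <- sprintf("%s_%02d", gsub("\\s+", "", label), seq_len(spec$groups$n[g]))
    fam <- evolve_family(templates[[arch]]$record, templates[[arch]]$truth,
                         spec, label, ids)
    records <- c(records, fam$records)
    truth <- c(truth, fam$truth)
    pieces_by_arch[[arch]] <- c(pieces_by_arch[[arch]], fam$pieces)
  }
  alignments <- list()
  anchor_columns <- list()
  for (arch in architectures) {
    tl <- nchar(templates[[arch]]$record$sequence)
    pa <- pieces_to_alignment(pieces_by_arch[[arch]], tl)
    alignments[[arch]] <- alignment_block(pa$rows)
    anchor_columns[[arch]] <- vapply(templates[[arch]]$truth$anchors,
                                     pa$column_of, integer(1L))
  }
  structure(list(records = records, truth = truth, alignments = alignments,
                 anchor_columns = anchor_columns, templates = templates,
                 spec = spec),
            class = "synthetic_family")
}

#' @export
print.synthetic_family <- function(x, ...) {
  cat(sprintf("<synthetic_family> %d sequences in %d group(s), seed %d\n",
              length(x$records), nrow(x$spec$groups), x$spec$seed))
  invisible(x)
}

#' Build an anchor map for a single pre-anchored sequence
#'
#' Convenience constructor for resolving histidine-relative coordinates on
#' one sequence whose anchor residue indices are already known (no family
#' alignment involved). Each anchor position must hold a histidine.
#'
#' @param record A [protein_record()].
#' @param anchors Four increasing 1-based residue indices of H1..H4.
#' @return An `anchor_map` covering just this sequence.
#' @export
single_sequence_anchor_map <- function(record, anchors) {
  anchors <- as.integer(anchors)
  if (length(anchors) != 4L || is.unsorted(anchors, strictly = TRUE)) {
    stop("'anchors' must be 4 strictly increasing residue indices")
  }
  chars <- strsplit(record$sequence, "")[[1L]]
  if (any(anchors < 1L | anchors > length(chars)) ||
      any(chars[anchors] != "H")) {
    stop("every anchor index must hold a histidine")
  }
  structure(list(anchor_columns = anchors,
                 per_sequence = stats::setNames(list(anchors), record$id),
                 his_fraction = rep(1, 4L),
                 sequences = stats::setNames(record$sequence, record$id)),
            class = "anchor_map")
}

#' Synthetic stand-in for the duodenal cytochrome b561 sequence
#'
#' Builds a single-domain template carrying the full ferric-reductase
#' residue catalog (and nothing group-specific) at the canonical anchor
#' register 50/86/120/159. This is a *synthetic* construction — the residues
#' known to matter are planted at their reported positions on a generated
#' hydrophobic scaffold; it is not the natural protein sequence.
#'
#' @param seed Integer seed for the scaffold residues.
#' @return List with `record`, `anchors` (50/86/120/159), and `map` (a
#'   single-sequence `anchor_map`).
#' @export
synthetic_dcytb <- function(seed = 1L) {
  catalog <- c(checklist_catalog()$core4, checklist_catalog()$supporting)
  sites <- lapply(names(catalog), function(pos) {
    list(pos = pos, residues = catalog[[pos]][1L], groups = NULL)
  })
  sites <- c(sites, list(
    list(pos = "H3-4", residues = "M", groups = NULL),   # loop-anchoring Met
    list(pos = "H4+21", residues = "E", groups = NULL)   # heme propionate Glu
  ))
  spec <- family_spec(groups = data.frame(label = "Dcytb-like", n = 1L,
                                          architecture = "single-domain",
                                          stringsAsFactors = FALSE),
                      conserved_sites = sites, planted_motifs = list(),
                      site_mutation_rate = 0, loop_indel_rate = 0,
                      seed = seed)
  set.seed(spec$seed)
  tpl <- make_template(spec, "single-domain")
  record <- protein_record("Dcytb_synthetic", tpl$record$sequence,
                           "synthetic Dcytb-like reference (catalog residues planted)")
  list(record = record, anchors = tpl$truth$anchors,
       truth = tpl$truth,
       map = single_sequence_anchor_map(record, tpl$truth$anchors))
}

#' Toy helix-bundle point sets for superposition tests
#'
#' Generates C-alpha-like points along three parallel ideal helices, applies
#' a random rigid transform to produce a second copy, and additionally
#' displaces a chosen number of points — the planted outliers.
#'
#' @param n_points Total number of points (>= 3).
#' @param outliers Number of displaced points in the transformed copy.
#' @param displacement Outlier displacement in Angstrom.
#' @param seed Integer seed.
#' @return List with matrices `a`, `b`, and `truth` (rotation, translation,
#'   outlier indices).
#' @export
make_helix_bundle <- function(n_points, outliers = 0L, displacement = 8,
                              seed = 1L) {
  if (n_points < 3L) stop("need at least 3 points")
  set.seed(seed)
  per <- ceiling(n_points / 3)
  pts <- do.call(rbind, lapply(0:2, function(h) {
    i <- seq_len(per)
    cbind(2.3 * cos(i * 100 * pi / 180) + 6 * h,
          2.3 * sin(i * 100 * pi / 180),
          1.5 * i)
  }))[seq_len(n_points), , drop = FALSE]
  # random proper rotation from a normalized quaternion
  q <- stats::rnorm(4L)
  q <- q / sqrt(sum(q^2))
  rot <- quaternion_rotation(q)
  trans <- stats::runif(3L, -10, 10)
  b <- sweep(pts %*% t(rot), 2L, trans, `+`)
  out_idx <- if (outliers > 0L) sort(sample(n_points, outliers)) else integer(0L)
  for (k in out_idx) {
    dir <- stats::rnorm(3L)
    b[k, ] <- b[k, ] + displacement * dir / sqrt(sum(dir^2))
  }
  list(a = pts, b = b,
       truth = list(rotation = rot, translation = trans, outliers = out_idx))
}

# rotation matrix of a unit quaternion (w, x, y, z)
#' @keywords internal
quaternion_rotation <- function(q) {
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3L, 3L, byrow = TRUE)
}

#' Serialize a point set as a toy C-alpha PDB table
#'
#' @param coords n x 3 matrix.
#' @param chain Chain id.
#' @return Atom data frame suitable for [write_structure()].
#' @export
points_as_ca_atoms <- function(coords, chain = "A") {
  coords <- as_xyz(coords)
  data.frame(chain = chain, resno = seq_len(nrow(coords)), resid = "ALA",
             elety = "CA", element = "C",
             x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
             het = FALSE, occupancy = 1, stringsAsFactors = FALSE)
}
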