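# Transmembrane topology from hydropathy, plus loop sidedness.
#
# The package assigns helix spans from Kyte-Doolittle sliding-window
# hydropathy. This is a sequence-only surrogate for reading helices off
# experimental or predicted structures: it keeps annotation download-free,
# and its parameters (window, cutoff, minimum length) are exposed.

#' Predict transmembrane segments by sliding-window hydropathy
#'
#' Window-averaged Kyte-Doolittle hydropathy is computed at every full-window
#' center; maximal runs of centers at or above `threshold`, widened by the
#' half-window they summarize, become candidate segments; segments separated
#' by fewer than 3 residues are merged, and segments shorter than `min_len`
#' are dropped.
#'
#' @param seq A [protein_record()] or plain sequence string.
#' @param window Odd window width (default 19).
#' @param threshold Hydropathy cutoff (default 1.6).
#' @param min_len Minimum segment length (default 15).
#' @return Object of class `tm_topology` with `segments` (matrix of start/end
#'   residue indices), and unset sidedness fields (see [assign_sidedness()]).
#' @export
predict_tm_segments <- function(seq, window = 19L, threshold = 1.6,
                                min_len = 15L) {
  s <- if (inherits(seq, "protein_record")) seq$sequence else seq
  window <- as.integer(window)
  if (window %% 2L != 1L) stop("'window' must be odd")
  n <- nchar(s)
  if (n < window) {
    stop(sprintf("sequence length %d shorter than window %d", n, window))
  }
  chars <- strsplit(s, "")[[1L]]
  h <- KYTE_DOOLITTLE[chars]
  h[is.na(h)] <- 0  # ambiguity codes contribute neutrally
  avg <- stats::filter(h, rep(1 / window, window), sides = 2)
  half <- (window - 1L) %/% 2L
  centers <- (half + 1L):(n - half)
  above <- centers[!is.na(avg[centers]) & avg[centers] >= threshold]
  runs <- runs_from_positions(above)
  # a center summarizes its full window: widen runs by the half-window, then
  # resolve collisions of widened neighbors at the hydropathy minimum between
  # them (merging only when no clear hydrophilic dip separates the runs)
  segs <- lapply(runs, function(r) {
    list(core = r, span = c(max(1L, r[1L] - half), min(n, r[2L] + half)))
  })
  if (length(segs) > 1L) {
    resolved <- list(segs[[1L]])
    for (s2 in segs[-1L]) {
      s1 <- resolved[[length(resolved)]]
      if (s2$span[1L] - s1$span[2L] - 1L < 3L) {
        between <- (s1$core[2L] + 1L):(s2$core[1L] - 1L)
        dip <- between[which.min(avg[between])]
        if (avg[dip] < threshold - 0.5) {
          s1$span[2L] <- min(s1$span[2L], dip - 1L)
          s2$span[1L] <- max(s2$span[1L], dip + 1L)
          resolved[[length(resolved)]] <- s1
          resolved[[length(resolved) + 1L]] <- s2
        } else {
          s1$core <- c(s1$core[1L], s2$core[2L])
          s1$span <- c(s1$span[1L], s2$span[2L])
          resolved[[length(resolved)]] <- s1
        }
      } else {
        resolved[[length(resolved) + 1L]] <- s2
      }
    }
    segs <- resolved
  }
  segs <- lapply(segs, `[[`, "span")
  if (length(segs) > 0L) {
    keep <- vapply(segs, function(r) r[2L] - r[1L] + 1L >= min_len, logical(1L))
    segs <- segs[keep]
  }
  segments <- if (length(segs) > 0L) {
    do.call(rbind, segs)
  } else {
    matrix(integer(0L), ncol = 2L)
  }
  colnames(segments) <- c("start", "end")
  structure(list(segments = segments,
                 n_terminus_side = NA_character_,
                 loop_sides = NULL,
                 core_register = NA_character_,
                 length = n),
            class = "tm_topology")
}

runs_from_positions <- function(pos) {
  if (length(pos) == 0L) return(list())
  breaks <- which(diff(pos) > 1L)
  starts <- pos[c(1L, breaks + 1L)]
  ends <- pos[c(breaks, length(pos))]
  mapply(function(a, b) c(a, b), starts, ends, SIMPLIFY = FALSE)
}

merge_close_runs <- function(runs, min_sep = 3L) {
  if (length(runs) < 2L) return(runs)
  out <- list(runs[[1L]])
  for (r in runs[-1L]) {
    last <- out[[length(out)]]
    if (r[1L] - last[2L] - 1L < min_sep) {
      out[[length(out)]] <- c(last[1L], r[2L])
    } else {
      out[[length(out) + 1L]] <- r
    }
  }
  out
}

#' @export
print.tm_topology <- function(x, ...) {
  cat(sprintf("<tm_topology> %d segment(s)%s\n", nrow(x$segments),
              if (!is.na(x$core_register)) paste0(", register ", x$core_register) else ""))
  if (nrow(x$segments) > 0L) {
    cat(paste(sprintf("  TM%d: %d-%d", seq_len(nrow(x$segments)),
                      x$segments[, 1L], x$segments[, 2L]), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Assign membrane sidedness and the core-domain register
#'
#' Single-domain cytb561s have cytoplasmic N- and C-termini with the heme
#' core in TM2-TM5; CYBDOM-class proteins have a non-cytoplasmic N-terminus
#' with the core in TM1-TM4. Sides strictly alternate across each segment.
#' As a structural sanity check, each anchor must lie in a segment and sit
#' nearer the segment terminus facing the compartment its heme occupies:
#' H1/H3 (non-cytoplasmic heme) toward the non-cytoplasmic face, H2/H4
#' (cytoplasmic heme) toward the cytoplasmic face. Violations set the
#' register to "undetermined" with a warning.
#'
#' @param topology A `tm_topology` from [predict_tm_segments()].
#' @param map An `anchor_map`.
#' @param seq_id Sequence id in the map.
#' @param architecture `"single-domain"` or `"cybdom"`.
#' @return The completed `tm_topology` (n_terminus_side, loop_sides,
#'   core_register filled in).
#' @export
assign_sidedness <- function(topology, map, seq_id,
                             architecture = c("single-domain", "cybdom")) {
  architecture <- match.arg(architecture)
  segs <- topology$segments
  n_seg <- nrow(segs)
  if (n_seg == 0L) stop("no transmembrane segments predicted")
  nterm <- if (architecture == "single-domain") "cytoplasmic" else "non-cytoplasmic"
  flip <- function(side) {
    if (side == "cytoplasmic") "non-cytoplasmic" else "cytoplasmic"
  }
  # side of the region after crossing k segments
  sides <- character(n_seg + 1L)
  sides[1L] <- nterm
  for (k in seq_len(n_seg)) sides[k + 1L] <- flip(sides[k])
  topology$n_terminus_side <- nterm
  topology$loop_sides <- sides[2:n_seg]  # inter-segment regions
  topology$c_terminus_side <- sides[n_seg + 1L]

  anchors <- anchor_indices(map, seq_id)
  seg_of <- vapply(anchors, function(i) {
    hit <- which(segs[, 1L] <= i & segs[, 2L] >= i)
    if (length(hit) == 1L) hit else NA_integer_
  }, integer(1L))
  if (anyNA(seg_of)) {
    warning(sprintf("anchor(s) %s outside any predicted segment: register undetermined",
                    paste(paste0("H", which(is.na(seg_of))), collapse = ", ")))
    topology$core_register <- "undetermined"
    return(topology)
  }
  # face each anchor is nearer to: entry side if nearer segment start
  near_side <- vapply(seq_along(anchors), function(j) {
    k <- seg_of[j]
    d_start <- anchors[j] - segs[k, 1L]
    d_end <- segs[k, 2L] - anchors[j]
    if (d_start <= d_end) sides[k] else sides[k + 1L]
  }, character(1L))
  want <- c("non-cytoplasmic", "cytoplasmic", "non-cytoplasmic", "cytoplasmic")
  if (!all(near_side == want)) {
    warning("anchor sidedness inconsistent with alternating topology: register undetermined")
    topology$core_register <- "undetermined"
    return(topology)
  }
  topology$core_register <- if (seg_of[1L] == 2L) {
    "TM2-TM5"
  } else if (seg_of[1L] == 1L) {
    "TM1-TM4"
  } else {
    "undetermined"
  }
  topology
}

#' Loop spans of the heme core domain
#'
#' Returns the three inter-helix loops between the segments housing H1-H2,
#' H2-H3 and H3-H4, in order cytoplasmic / non-cytoplasmic / cytoplasmic.
#'
#' @param topology A completed `tm_topology` (see [assign_sidedness()]).
#' @param map An `anchor_map`.
#' @param seq_id Sequence id.
#' @return List of three c(start, end) residue spans with a `sides` attribute.
#' @export
core_loops <- function(topology, map, seq_id) {
  if (is.na(topology$core_register) || topology$core_register == "undetermined") {
    stop("core register undetermined: cannot delimit core loops")
  }
  segs <- topology$segments
  anchors <- anchor_indices(map, seq_id)
  seg_of <- vapply(anchors, function(i) {
    which(segs[, 1L] <= i & segs[, 2L] >= i)
  }, integer(1L))
  loops <- lapply(1:3, function(j) {
    c(segs[seg_of[j], 2L] + 1L, segs[seg_of[j + 1L], 1L] - 1L)
  })
  attr(loops, "sides") <- c("cytoplasmic", "non-cytoplasmic", "cytoplasmic")
  loops
}
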