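# Ferric-reductase residue checklist derived from the duodenal cytochrome
# b561 (Dcytb) substrate-binding catalog, expressed in histidine-relative
# coordinates so it can be evaluated on any anchored family member.

# Each item: histidine-relative position -> accepted residue class. The
# classes are the substitution sets observed across confirmed ferric
# reductases and their close relatives, not a conservation guess:
# e.g. H2+21 accepts the asparagine of Dcytb and its conservative serine
# replacement; H4+25 accepts any bulky aromatic.
checklist_catalog <- function() {
  list(
    core4 = list(
      "H2+22" = "H",               # metal-coordinating histidine (His108)
      "H2+21" = c("N", "S"),       # Asn107 or conservative Ser
      "H3-3"  = "Y",               # Tyr117
      "H4+25" = c("F", "Y", "W")   # aromatic stacking with ascorbate (Phe184)
    ),
    supporting = list(
      "H1-3"  = "F",               # non-cytoplasmic ascorbate contact (Phe47)
      "H2-7"  = c("K", "R"),       # cytoplasmic ascorbate (Lys79)
      "H2-3"  = c("K", "R"),       # cytoplasmic ascorbate (Lys83)
      "H4-7"  = c("K", "R"),       # cytoplasmic ascorbate (Arg152)
      "H1+20" = c("R", "K"),       # heme A-propionate salt bridge (Arg70)
      "H3+14" = c("Q", "S", "T"),  # H4-positioning glutamine (Gln134)
      "H3-2"  = c("S", "T", "N"),  # heme A-propionate H-bond (Ser118)
      "H3-5"  = c("N", "H"),       # heme D-propionate H-bond (Asn115)
      "H3+2"  = "W",               # loop-stabilizing tryptophan (Trp122)
      "H3+4"  = c("G", "A", "S"),  # small heme-packing residues
      "H3+18" = c("G", "A", "S"),
      "H4+4"  = c("G", "A", "S"),
      "H4+18" = c("G", "A", "S")
    )
  )
}

#' Evaluate the ferric-reductase residue checklist
#'
#' Checks a sequence, anchored on its four conserved histidines, against the
#' residue catalog of a confirmed ferric reductase. The four
#' activity-critical items (H2+22 His, H2+21 Asn/Ser, H3-3 Tyr, H4+25
#' aromatic) form the `core4` verdict; the remaining heme- and
#' ascorbate-positioning items contribute to a catalog score. Items whose
#' offset leaves the sequence are marked unresolvable, not failed.
#'
#' @param seq A [protein_record()].
#' @param map An `anchor_map` covering the sequence.
#' @param catalog Optional replacement catalog in the shape of
#'   `cytb561anno:::checklist_catalog()` (users may override residue
#'   classes).
#' @return Object of class `checklist_report`: data frame `items` (position,
#'   tier, expected class, observed residue and index, status pass/fail/
#'   unresolvable), `core4_pass`, and `score` (passed / resolvable items
#'   over the full catalog).
#' @export
ferric_reductase_checklist <- function(seq, map, catalog = checklist_catalog()) {
  id <- if (inherits(seq, "protein_record")) seq$id else ""
  anchor_indices(map, id)  # fail early on unmapped anchors
  eval_tier <- function(items, tier) {
    rows <- lapply(names(items), function(pos) {
      expected <- items[[pos]]
      obs <- tryCatch(resolve_relpos(map, id, pos), error = function(e) NULL)
      if (is.null(obs)) {
        data.frame(position = pos, tier = tier,
                   expected = paste(expected, collapse = "/"),
                   index = NA_integer_, observed = NA_character_,
                   status = "unresolvable", stringsAsFactors = FALSE)
      } else {
        data.frame(position = pos, tier = tier,
                   expected = paste(expected, collapse = "/"),
                   index = obs$index, observed = obs$residue,
                   status = if (obs$residue %in% expected) "pass" else "fail",
                   stringsAsFactors = FALSE)
      }
    })
    do.call(rbind, rows)
  }
  items <- rbind(eval_tier(catalog$core4, "core4"),
                 eval_tier(catalog$supporting, "supporting"))
  core <- items[items$tier == "core4", ]
  resolvable <- items$status != "unresolvable"
  structure(list(
    seq_id = id,
    items = items,
    core4_pass = all(core$status == "pass"),
    score = c(passed = sum(items$status == "pass"),
              resolvable = sum(resolvable),
              total = nrow(items))
  ), class = "checklist_report")
}

#' @export
print.checklist_report <- function(x, ...) {
  cat(sprintf("<checklist_report> %s: core4 %s; %d/%d catalog items pass\n",
              x$seq_id, if (x$core4_pass) "PASS" else "FAIL",
              x$score[["passed"]], x$score[["resolvable"]]))
  fails <- x$items[x$items$status == "fail", ]
  if (nrow(fails) > 0L) {
    cat("  failed:",
        paste(sprintf("%s (%s, saw %s)", fails$position, fails$expected,
                      fails$observed), collapse = "; "), "\n")
  }
  invisible(x)
}
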