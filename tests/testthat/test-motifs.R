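test_that("motif patterns parse into position constraints", {
  spec <- motif_spec("kxh", "KXXXXKXH")
  expect_length(spec$positions, 8L)
  expect_null(spec$positions[[2L]])
  expect_equal(spec$positions[[1L]], "K")

  dil <- motif_spec("dileucine", "(D/E)XXXL(L/I)")
  expect_length(dil$positions, 6L)
  expect_equal(dil$positions[[1L]], c("D", "E"))
  expect_equal(dil$positions[[6L]], c("L", "I"))

  expect_error(motif_spec("bad", "K(X/"), "unbalanced")
  expect_error(motif_spec("bad", "K1H"), "illegal pattern")
  expect_error(motif_spec("short", "KX"), ">= 3")
})

test_that("scanning finds the aspartate-pocket and loop motifs", {
  seq <- paste0(strrep("A", 280L), "SVDAAMGKD", strrep("A", 20L))
  hits <- scan_motif(protein_record("x", seq), builtin_motif("SXDXXMGXD"))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 281L)
  expect_equal(hits$end, 289L)
  expect_equal(substr(seq, 286L, 286L), "M")

  hits2 <- scan_motif(protein_record("y", "KAAAAKAH"), builtin_motif("KXXXXKXH"))
  expect_equal(hits2$start, 1L)
  expect_equal(hits2$end, 8L)

  # overlapping matches are all reported
  hits3 <- scan_motif(protein_record("z", "KKAAAKKHH"),
                      builtin_motif("KXXXXKXH"))
  expect_equal(hits3$start, c(1L, 2L))
})

test_that("region constraints and ambiguity codes are strict", {
  seq <- paste0("KAAAAKAH", strrep("D", 30L))
  rec <- protein_record("r", seq)
  expect_equal(nrow(scan_motif(rec, builtin_motif("KXXXXKXH"), c(9L, 38L))), 0L)
  expect_equal(nrow(scan_motif(rec, builtin_motif("KXXXXKXH"), c(1L, 8L))), 1L)
  expect_error(scan_motif(rec, builtin_motif("KXXXXKXH"), c(0L, 10L)), "region")

  # X in the sequence satisfies wildcards but no literal position
  expect_equal(nrow(scan_motif(protein_record("a", "KXAAAKAH"),
                               builtin_motif("KXXXXKXH"))), 1L)
  expect_equal(nrow(scan_motif(protein_record("b", "XAAAAKAH"),
                               builtin_motif("KXXXXKXH"))), 0L)
})

test_that("scanners agree with the exhaustive oracle on random sequences", {
  set.seed(61L)
  patterns <- c("KXXXXKXH", "EDXXLL", "(D/E)XXXL(L/I)", "DXXLL", "SXDXXMGXD")
  for (k in 1:40) {
    seq <- paste(sample(c(AA20, "X", "B"), 200L, replace = TRUE,
                        prob = c(rep(1, 20L), 0.3, 0.1)), collapse = "")
    for (p in patterns) {
      got <- scan_motif(protein_record("r", seq), motif_spec(p, p))$start
      expect_equal(got, scan_oracle(seq, p), info = p)
    }
  }
})

test_that("dileucine signals are confined to the post-TM tail and ranked", {
  topo <- structure(list(segments = matrix(c(5L, 30L), 1L,
                                           dimnames = list(NULL, c("start", "end"))),
                         length = 60L), class = "tm_topology")
  rec <- protein_record("t", paste0(strrep("L", 30L), strrep("A", 20L), "EDSALL",
                                    "AAAA"))
  hits <- dileucine_signals(rec, topo)
  expect_true("EDXXLL" %in% hits$motif)
  expect_false("(D/E)XXXL(L/I)" %in% hits$motif)  # upgraded to the exact form

  rec2 <- protein_record("t2", paste0(strrep("L", 30L), strrep("A", 20L),
                                      "DAALL", "AAAA"))
  hits2 <- dileucine_signals(rec2, topo)
  expect_equal(hits2$motif, "DXXLL")

  # signal upstream of the last TM segment is invisible
  rec3 <- protein_record("t3", paste0("EDSALL", strrep("L", 30L),
                                      strrep("A", 20L)))
  topo3 <- structure(list(segments = matrix(c(7L, 36L), 1L,
                                            dimnames = list(NULL, c("start", "end"))),
                          length = 56L), class = "tm_topology")
  expect_equal(nrow(dileucine_signals(rec3, topo3)), 0L)

  # no tail at all
  rec4 <- protein_record("t4", strrep("L", 30L))
  topo4 <- structure(list(segments = matrix(c(1L, 30L), 1L,
                                            dimnames = list(NULL, c("start", "end"))),
                          length = 30L), class = "tm_topology")
  expect_message(h4 <- dileucine_signals(rec4, topo4), "tail")
  expect_equal(nrow(h4), 0L)
})

test_that("the loop motif scan respects the H2..H3 window and register", {
  fam <- simulate_family(family_spec(seed = 21L))
  m <- find_histidine_anchors(fam$alignments[["single-domain"]])
  ids <- vapply(fam$records, `[[`, "", "id")
  for (id in grep("^Group4A", ids, value = TRUE)) {
    rec <- fam$records[[which(ids == id)]]
    truth <- fam$truth[[id]]$motifs[[1L]]
    hits <- kxh_site(rec, m)
    if (truth$planted) {
      expect_equal(nrow(hits), 1L)
      expect_equal(hits$start, truth$span[1L])
      expect_true(hits$canonical_register)
    } else {
      expect_equal(nrow(hits), 0L)
    }
  }

  # the same motif planted in the H1..H2 loop is out of region
  d <- synthetic_dcytb(seed = 44L)
  s <- d$record$sequence
  substr(s, 60L, 67L) <- "KAAAAKAH"  # inside H1..H2, not H2..H3
  rec <- protein_record("shifted", s)
  # anchor histidines unchanged
  map <- single_sequence_anchor_map(rec, d$anchors)
  expect_equal(nrow(kxh_site(rec, map)), 0L)
})

test_that("DOMON heme ligands require a unique pocket match", {
  base <- paste0(strrep("A", 19L), "SVDAAMGKD", strrep("A", 22L))
  rec <- protein_record("domon1", base)
  got <- suppressMessages(domon_heme_ligands(rec, c(1L, 50L)))
  expect_equal(got$met_index, 25L)
  expect_true(is.na(got$his_index))

  expect_equal(suppressMessages(
    domon_heme_ligands(protein_record("none", strrep("A", 50L)),
                       c(1L, 50L)))$met_index, NA_integer_)

  two <- protein_record("two", paste0("SVDAAMGKD", "SVDAAMGKD",
                                      strrep("A", 10L)))
  expect_true(is.na(suppressMessages(
    domon_heme_ligands(two, c(1L, 28L)))$met_index))

  # alignment mode: planted His column downstream of the Met
  rows <- c(domon1 = paste0(base, "H", strrep("A", 5L)),
            domon2 = paste0(strrep("A", 19L), "SQDTTMGPD", strrep("A", 22L),
                            "H", strrep("A", 5L)),
            domon3 = paste0(strrep("C", 19L), "SQDTTMGPD", strrep("C", 22L),
                            "H", strrep("C", 5L)))
  aln <- alignment_block(rows)
  got2 <- domon_heme_ligands(protein_record("domon1", base), c(1L, 50L),
                             aln = aln)
  expect_equal(got2$met_index, 25L)
  expect_equal(got2$his_index, 51L)
})

test_that("cysteine loop profiles flag the double-cysteine pattern", {
  # without substitution noise the planted doublets are recovered exactly
  clean_spec <- family_spec(
    groups = data.frame(label = c("Nemy", "CG1275", "Group 4B"),
                        n = c(6L, 4L, 4L),
                        architecture = "single-domain"),
    site_mutation_rate = 0, seed = 33L)
  fam <- simulate_family(clean_spec)
  m <- find_histidine_anchors(fam$alignments[["single-domain"]])
  ids <- vapply(fam$records, `[[`, "", "id")
  for (id in grep("^Nemy", ids, value = TRUE)) {
    rec <- fam$records[[which(ids == id)]]
    topo <- assign_sidedness(predict_tm_segments(rec), m, id, "single-domain")
    prof <- cysteine_loop_profile(rec, m, topo)
    expect_equal(prof$sides, c("cytoplasmic", "non-cytoplasmic", "cytoplasmic"))
    expect_true(prof$double_cys[1L], info = id)
    expect_true(prof$double_cys[3L], info = id)
    expect_true(prof$nemy_like, info = id)
  }
  for (id in grep("^CG1275", ids, value = TRUE)) {
    rec <- fam$records[[which(ids == id)]]
    topo <- assign_sidedness(predict_tm_segments(rec), m, id, "single-domain")
    expect_false(cysteine_loop_profile(rec, m, topo)$nemy_like, info = id)
  }

  # under the default 20% substitution noise, most sequences stay flaggable
  noisy <- simulate_family(family_spec(seed = 33L))
  mn <- find_histidine_anchors(noisy$alignments[["single-domain"]])
  nids <- vapply(noisy$records, `[[`, "", "id")
  flags <- vapply(grep("^Nemy", nids, value = TRUE), function(id) {
    rec <- noisy$records[[which(nids == id)]]
    topo <- suppressWarnings(
      assign_sidedness(predict_tm_segments(rec), mn, id, "single-domain"))
    if (!identical(topo$core_register, "TM2-TM5")) return(NA)
    cysteine_loop_profile(rec, mn, topo)$nemy_like
  }, logical(1L))
  expect_gte(mean(flags, na.rm = TRUE), 0.6)

  # a cysteine-free sequence is never flagged
  d <- synthetic_dcytb(seed = 2L)
  topo <- assign_sidedness(predict_tm_segments(d$record), d$map, d$record$id,
                           "single-domain")
  prof <- cysteine_loop_profile(d$record, d$map, topo)
  expect_equal(prof$cys_count, c(0L, 0L, 0L))
  expect_false(prof$nemy_like)
})
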