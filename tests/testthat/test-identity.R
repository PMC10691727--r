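test_that("global alignment reproduces hand-computed affine-gap scores", {
  self <- align_pair("MKHACDEF", "MKHACDEF")
  expect_equal(self$row_a, "MKHACDEF")
  expect_equal(self$row_b, "MKHACDEF")

  # ACDE vs ACE: best is AC-E / one gap; BLOSUM62 4 + 9 + 5 - (10 + 1) = 7
  al <- align_pair("ACDE", "ACE")
  expect_equal(al$score, 7)
  expect_equal(al$row_b, "AC-E")
  expect_equal(sum(strsplit(al$row_b, "")[[1L]] == "-"), 1L)
})

test_that("alignment scores are symmetric", {
  recs <- random_records(10L, len = 30L, seed = 8L)
  for (k in 1:5) {
    a <- recs[[k]]$sequence
    b <- recs[[k + 5L]]$sequence
    expect_equal(align_pair(a, b)$score, align_pair(b, a)$score)
  }
})

test_that("percent identity uses the both-non-gap denominator", {
  expect_equal(percent_identity("ACDEF", "ACDEF"), 100)
  expect_equal(percent_identity("ACDEF", "ACDFF"), 80)
  expect_equal(percent_identity("A-CD", "AXCD"), 100)  # 3 shared, 3 identical
  expect_warning(v <- percent_identity("--A", "A--"), "undefined")
  expect_true(is.na(v))
  expect_error(percent_identity("AC", "ACD"), "equal length")

  # brute-force column-count oracle on random gapped rows
  set.seed(77L)
  for (k in 1:20) {
    n <- 40L
    a <- sample(c(AA20, "-"), n, replace = TRUE, prob = c(rep(1, 20L), 5))
    b <- sample(c(AA20, "-"), n, replace = TRUE, prob = c(rep(1, 20L), 5))
    shared <- which(a != "-" & b != "-")
    expected <- if (length(shared) == 0L) NA_real_ else {
      100 * sum(a[shared] == b[shared]) / length(shared)
    }
    got <- suppressWarnings(percent_identity(paste(a, collapse = ""),
                                             paste(b, collapse = "")))
    expect_equal(got, expected)
  }
})

test_that("percent identity is symmetric and gap-column invariant", {
  set.seed(5L)
  for (k in 1:10) {
    a <- paste(sample(c(AA20, "-"), 30L, replace = TRUE), collapse = "")
    b <- paste(sample(AA20, 30L, replace = TRUE), collapse = "")
    expect_equal(percent_identity(a, b), percent_identity(b, a))
    expect_equal(percent_identity(paste0(a, "---"), paste0(b, "---")),
                 percent_identity(a, b))
  }
})

test_that("span intersection follows the common-region rule", {
  expect_equal(common_region(list(c(44L, 179L), c(40L, 185L))), c(44L, 179L))
  expect_equal(common_region(list(c(7L, 20L))), c(7L, 20L))
  expect_error(common_region(list(c(1L, 10L), c(20L, 30L))), "no common region")
})

test_that("identity matrices are complete with a 100 diagonal", {
  recs <- random_records(4L, len = 50L, seed = 12L)
  mat <- identity_matrix(recs, recs)
  expect_equal(unname(diag(mat$values)), rep(100, 4L))
  expect_true(all(!is.na(mat$values)))

  # restricting a self-comparison to any common sub-span stays 100
  spans <- list(seq01 = c(10L, 40L))
  mat2 <- identity_matrix(recs[1L], recs[1L], spans = spans)
  expect_equal(unname(mat2$values[1L, 1L]), 100)
})

test_that("matrix extraction from a shared MSA matches row-pair identity", {
  aln <- alignment_block(c(a = "MKH-ACDE", b = "MKHYACDE", c = "MKH-AADE"))
  mat <- identity_matrix_from_alignment(aln, c("a", "b"), c("b", "c"))
  expect_equal(unname(mat$values["a", "b"]), percent_identity(aln$rows[["a"]],
                                                              aln$rows[["b"]]))
  expect_equal(unname(mat$values["b", "b"]), 100)
})

test_that("best match uses the fixed column order on ties", {
  vals <- matrix(c(30, 30, 30, 20, 25, 30), 2L, 3L, byrow = TRUE,
                 dimnames = list(c("r1", "r2"), c("Dcytb", "Lcytb", "CGcytb")))
  mat <- identity_matrix_object(vals)
  expect_equal(best_match(mat, "r1")$reference, "Dcytb")
  expect_equal(best_match(mat, "r2")$reference, "CGcytb")
  expect_error(best_match(mat, "zz"), "unknown row")
})

test_that("fixture best matches reproduce the published classification", {
  fx <- read_similarity_fixture()
  bm1 <- best_match(fx$matrix, "NP_611079.2")
  expect_equal(bm1$reference, "SDR2")
  expect_equal(bm1$identity, 37.0)
  bm2 <- best_match(fx$matrix, "NP_728727.1")
  expect_equal(bm2$reference, "Dcytb")
  expect_equal(bm2$identity, 45.7)

  gs <- summarize_groups(fx$matrix, fx$group)
  # every CYBDOM-class row best-matches SDR2
  cg8399 <- gs$best[gs$best$group == "CG8399", ]
  expect_true(all(cg8399$reference == "SDR2"))
  # Dcytb-like rows best-match one of the three close human relatives
  dlike <- gs$best[gs$best$group %in% c("CG1275", "Nemy"), ]
  expect_true(all(dlike$reference %in% c("Dcytb", "CGcytb", "Lcytb")))
})

test_that("the more-similar-to-human flag is strict and monotone", {
  h <- identity_matrix_object(matrix(c(30, 10), 1L, 2L,
                                     dimnames = list("r", c("TScytb", "Dcytb"))))
  dm_hi <- identity_matrix_object(matrix(c(25, 12), 1L, 2L,
                                         dimnames = list("r", c("d1", "d2"))))
  expect_true(flag_group4a(h, dm_hi)[["r"]])
  dm_eq <- identity_matrix_object(matrix(c(30, 12), 1L, 2L,
                                         dimnames = list("r", c("d1", "d2"))))
  expect_false(flag_group4a(h, dm_eq)[["r"]])  # ties do not flag
  # raising any conspecific cell above the human max clears the flag
  dm_up <- identity_matrix_object(matrix(c(25, 31), 1L, 2L,
                                         dimnames = list("r", c("d1", "d2"))))
  expect_false(flag_group4a(h, dm_up)[["r"]])
  expect_error(flag_group4a(h, identity_matrix_object(
    matrix(1, 1L, 1L, dimnames = list("q", "d1")))), "missing")
})

test_that("group summaries count and range correctly", {
  vals <- matrix(c(50, 10, 20, 60, 5, 40), 3L, 2L, byrow = TRUE,
                 dimnames = list(c("a", "b", "c"), c("X", "Y")))
  mat <- identity_matrix_object(vals)
  gs <- summarize_groups(mat, c(a = "g1", b = "g1", c = "solo"))
  expect_equal(unname(gs$groups$g1$best_counts[["X"]]), 1L)
  expect_equal(unname(gs$groups$g1$best_counts[["Y"]]), 1L)
  expect_equal(unname(gs$groups$g1$best_range), c(50, 60))
  expect_equal(unname(gs$groups$solo$best_range), c(40, 40))
  expect_error(summarize_groups(mat, c(a = "g1", b = "g1")), "unlabeled")
})

test_that("synthetic divergence matches its planted substitution rate", {
  # no conserved sites or motifs: expected identity to template is 1 - m
  # (up to the four immutable anchors)
  idents <- vapply(1:8, function(s) {
    spec <- family_spec(
      groups = data.frame(label = "g", n = 1L, architecture = "single-domain"),
      conserved_sites = list(), planted_motifs = list(),
      site_mutation_rate = 0.2, loop_indel_rate = 0, seed = s)
    fam <- simulate_family(spec)
    al <- align_pair(fam$records[[1L]], fam$templates[["single-domain"]]$record)
    percent_identity(al$row_a, al$row_b)
  }, numeric(1L))
  expect_lt(abs(mean(idents) - 80), 3)
})
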