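aln_from_columns <- function(cols) {
  # cols: list of character vectors, one per column, all same length
  n <- length(cols[[1L]])
  rows <- vapply(seq_len(n), function(i) {
    paste(vapply(cols, `[`, "", i), collapse = "")
  }, character(1L))
  names(rows) <- sprintf("s%02d", seq_len(n))
  alignment_block(rows)
}

test_that("consensus symbols follow the modal/tie/gap rules", {
  aln <- aln_from_columns(list(
    c("A", "A", "A", "A"),   # unanimous
    c("A", "A", "C", "C"),   # two-way tie
    c("A", "-", "-", "-"),   # gap-modal
    c("A", "A", "C", "-")    # A modal despite gap
  ))
  logo <- consensus_logo(aln)
  expect_equal(logo$consensus, c("A", "+", "-", "A"))
  expect_equal(sum(logo$frequencies[, 1L]), 1)
  expect_equal(unname(logo$frequencies["A", 1L]), 1)
  expect_equal(unname(logo$frequencies["-", 3L]), 0.75)
})

test_that("property-count conservation matches the brute-force oracle", {
  expect_equal(amas_conservation(aln_from_columns(list(rep("G", 5L)))), 11L)

  cases <- list(c("I", "L", "V"), c("D", "K"), c("F", "Y", "W"),
                c("A", "G", "S"), c("D", "E"), c("P", "G"),
                c("K", "R", "H"), c("C", "M"))
  for (resset in cases) {
    col <- rep(resset, length.out = 6L)
    got <- amas_conservation(aln_from_columns(list(col)))
    expect_equal(got, amas_oracle(resset), info = paste(resset, collapse = ""))
  }

  # exhaustive over all three-residue sets
  combos <- combn(AA20, 3L)
  for (j in seq_len(ncol(combos))) {
    col <- combos[, j]
    expect_equal(amas_conservation(aln_from_columns(list(col))),
                 amas_oracle(col))
  }
})

test_that("gaps reduce the property score and cap the identity bonus", {
  expect_equal(amas_conservation(aln_from_columns(list(c("G", "G", "-")))), 9L)
  expect_equal(amas_conservation(aln_from_columns(list(c("-", "-", "-")))), 0L)
  with_gap <- amas_conservation(aln_from_columns(list(c("I", "L", "-"))))
  without <- amas_conservation(aln_from_columns(list(c("I", "L", "L"))))
  expect_equal(with_gap, without - 1L)
})

test_that("conservation scores never rise when a column diversifies", {
  set.seed(23L)
  for (k in 1:25) {
    base <- sample(AA20, sample(1:4, 1L))
    extra <- sample(setdiff(AA20, base), 1L)
    col1 <- rep(base, length.out = 6L)
    col2 <- c(col1, extra)
    s1 <- amas_conservation(aln_from_columns(list(col1)))
    s2 <- amas_conservation(aln_from_columns(list(col2)))
    expect_lte(s2, s1)
  }
})

test_that("entropy z-scores standardize and rank conservation", {
  set.seed(4L)
  n_rows <- 20L
  cols <- c(list(rep("W", n_rows)),            # invariant
            list(AA20),                        # maximally diverse
            lapply(1:30, function(i) sample(AA20, n_rows, replace = TRUE)))
  aln <- aln_from_columns(cols)
  z <- al2co_standardized(aln)
  expect_equal(which.max(z$z), 1L)
  expect_equal(which.min(z$z), 2L)
  expect_equal(mean(z$z), 0, tolerance = 1e-10)
  expect_equal(sd(z$z), 1, tolerance = 1e-10)
  expect_true(all(z$z_display >= -1.5 & z$z_display <= 1.5))

  flat <- aln_from_columns(list(rep("A", 4L), rep("C", 4L)))
  expect_warning(zf <- al2co_standardized(flat), "identical entropy")
  expect_equal(zf$z, c(0, 0))
})

test_that("group consensus equals the row-subset profile", {
  set.seed(9L)
  rows <- vapply(1:8, function(i) {
    paste(sample(AA20, 30L, replace = TRUE), collapse = "")
  }, character(1L))
  names(rows) <- sprintf("s%02d", 1:8)
  aln <- alignment_block(rows)

  one_group <- group_consensus(aln, setNames(rep("all", 8L), names(rows)))
  expect_equal(one_group$all$profile$consensus, consensus_logo(aln)$consensus)
  expect_equal(one_group$all$amas, amas_conservation(aln))

  labels <- setNames(c("solo", rep("rest", 7L)), names(rows))
  gc <- group_consensus(aln, labels)
  expect_equal(paste(gc$solo$profile$consensus, collapse = ""), rows[["s01"]])
  expect_true(all(gc$solo$amas == 11L))
  expect_error(group_consensus(aln, labels[-1L]), "unlabeled")
})

test_that("scores are invariant under row permutation and duplication", {
  set.seed(15L)
  rows <- vapply(1:6, function(i) {
    paste(sample(c(AA20, "-"), 25L, replace = TRUE), collapse = "")
  }, character(1L))
  names(rows) <- sprintf("s%02d", 1:6)
  aln <- alignment_block(rows)
  perm <- alignment_block(rows[sample(6L)])
  expect_equal(amas_conservation(aln), amas_conservation(perm))
  expect_equal(consensus_logo(aln)$consensus, consensus_logo(perm)$consensus)
  dup <- alignment_block(setNames(c(rows, rows), c(names(rows),
                                                   paste0(names(rows), "b"))))
  expect_equal(amas_conservation(aln), amas_conservation(dup))
  expect_equal(consensus_logo(aln)$consensus, consensus_logo(dup)$consensus)
})

test_that("anchor columns are the reliably invariant columns of a family", {
  for (s in c(2L, 17L)) {
    spec <- family_spec(
      groups = data.frame(label = "g", n = 10L, architecture = "single-domain"),
      conserved_sites = list(), planted_motifs = list(),
      site_mutation_rate = 0.3, loop_indel_rate = 0, seed = s)
    fam <- simulate_family(spec)
    aln <- fam$alignments[["single-domain"]]
    scores <- amas_conservation(aln)
    anchor_cols <- fam$anchor_columns[["single-domain"]]
    expect_true(all(scores[anchor_cols] == 11L))
    other <- scores[-anchor_cols]
    expect_gte(mean(other < 11L), 0.95)
  }
})
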