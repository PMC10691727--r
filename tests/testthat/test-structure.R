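test_that("rigid superposition recovers exact transforms", {
  set.seed(41L)
  a <- matrix(rnorm(60L), ncol = 3L)
  fit0 <- kabsch(a, a)
  expect_equal(fit0$rmsd_all, 0, tolerance = 1e-12)
  expect_equal(fit0$rotation, diag(3L), tolerance = 1e-9)

  bundle <- make_helix_bundle(40L, seed = 2L)
  fit <- kabsch(bundle$a, bundle$b)
  expect_lt(fit$rmsd_all, 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  # the fit inverts the generating transform
  expect_equal(fit$rotation, t(bundle$truth$rotation), tolerance = 1e-6)
})

test_that("superposition RMSD matches the quaternion oracle", {
  set.seed(52L)
  for (k in 1:5) {
    a <- matrix(rnorm(150L), ncol = 3L)
    b <- matrix(rnorm(150L), ncol = 3L)
    expect_equal(kabsch(a, b)$rmsd_all, quaternion_rmsd(a, b),
                 tolerance = 1e-9)
  }
})

test_that("RMSD is invariant under a common rigid transform", {
  set.seed(63L)
  a <- matrix(rnorm(90L), ncol = 3L)
  b <- a + matrix(rnorm(90L, sd = 0.5), ncol = 3L)
  base <- kabsch(a, b)$rmsd_all
  q <- rnorm(4L); q <- q / sqrt(sum(q^2))
  rot <- cytb561anno:::quaternion_rotation(q)
  shift <- runif(3L, -5, 5)
  a2 <- sweep(a %*% t(rot), 2L, shift, `+`)
  b2 <- sweep(b %*% t(rot), 2L, shift, `+`)
  expect_equal(kabsch(a2, b2)$rmsd_all, base, tolerance = 1e-9)
})

test_that("iterative pruning drops exactly the planted outliers", {
  bundle <- make_helix_bundle(60L, outliers = 0L, seed = 7L)
  clean <- prune_superpose(bundle$a, bundle$b)
  expect_equal(clean$n_pruned, 60L)
  expect_lt(clean$rmsd_pruned, 1e-9)

  noisy <- make_helix_bundle(60L, outliers = 5L, displacement = 8, seed = 7L)
  fit <- prune_superpose(noisy$a, noisy$b)
  expect_equal(setdiff(seq_len(60L), fit$retained), noisy$truth$outliers)
  expect_equal(fit$n_pruned, 55L)
  expect_lt(fit$rmsd_pruned, 1e-6)
  expect_gt(fit$rmsd_all, 1)
  expect_lte(fit$rmsd_pruned, fit$rmsd_all + 1e-9)

  # pruning is idempotent on the retained set
  again <- prune_superpose(noisy$a[fit$retained, ], noisy$b[fit$retained, ])
  expect_equal(again$n_pruned, 55L)
  expect_lt(abs(again$rmsd_pruned - fit$rmsd_pruned), 1e-9)
})

toy_model <- function(df) {
  structure(list(atoms = df, source = "in-memory"), class = "structure_model")
}

two_atom_model <- function(d, el = c("C", "C")) {
  toy_model(data.frame(
    chain = "A", resno = 1:2, resid = c("ALA", "GLY"), elety = el,
    element = el, x = c(0, d), y = 0, z = 0, occupancy = 1, het = FALSE,
    stringsAsFactors = FALSE))
}

test_that("van der Waals contacts honor the overlap boundary", {
  # r_C + r_C = 3.4; at d = 3.8 the overlap is exactly the -0.4 cutoff
  cs <- vdw_contacts(two_atom_model(3.8), 1L, 2L)
  expect_equal(nrow(cs$pairs), 1L)
  expect_equal(cs$pairs$overlap, -0.4)
  expect_equal(nrow(vdw_contacts(two_atom_model(3.81), 1L, 2L)$pairs), 0L)
  expect_error(vdw_contacts(two_atom_model(3.8), 1L, 1L), "disjoint")
  expect_error(vdw_contacts(two_atom_model(3.8, el = c("C", "QQ")), 1L, 2L),
               "QQ")
})

test_that("contact detection equals the exhaustive pairwise oracle", {
  set.seed(74L)
  n <- 120L
  df <- data.frame(
    chain = "A", resno = seq_len(n), resid = "ALA", elety = "CA",
    element = sample(c("C", "N", "O", "S"), n, replace = TRUE),
    x = runif(n, 0, 18), y = runif(n, 0, 18), z = runif(n, 0, 18),
    occupancy = 1, het = FALSE, stringsAsFactors = FALSE)
  model <- toy_model(df)
  ia <- 1:60; ib <- 61:120
  cs <- vdw_contacts(model, ia, ib)
  got <- sort(paste(cs$pairs$atom_a, cs$pairs$atom_b))
  radii <- cytb561anno:::VDW_RADII
  want <- character(0L)
  for (i in ia) for (j in ib) {
    d <- sqrt(sum((df[i, c("x", "y", "z")] - df[j, c("x", "y", "z")])^2))
    if (radii[[df$element[i]]] + radii[[df$element[j]]] - d >= -0.4) {
      want <- c(want, paste(i, j))
    }
  }
  expect_equal(got, sort(want))
})

hb_case <- function(o_pos, o_ante_offset) {
  # residue 1: donor N at the origin with a C antecedent behind it;
  # residue 2: acceptor O with its own C antecedent (for the reverse scan)
  data.frame(
    chain = "A", resno = c(1L, 1L, 2L, 2L), resid = c("ALA", "ALA", "LIG", "LIG"),
    elety = c("C", "N", "O", "C1"), element = c("C", "N", "O", "C"),
    x = c(-1.4, 0, o_pos[1L], o_pos[1L] + o_ante_offset[1L]),
    y = c(0, 0, o_pos[2L], o_pos[2L] + o_ante_offset[2L]),
    z = 0, occupancy = 1, het = c(FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
}

test_that("heavy-atom hydrogen bonds follow the distance/angle criterion", {
  # linear N...O at 2.9 A; the O's antecedent sits perpendicular, so only
  # the N-donor direction satisfies the angle criterion
  df <- hb_case(c(2.9, 0), c(0, 1.4))
  hb <- hbonds(toy_model(df), 1:2, 3:4)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$donor, 2L)
  expect_equal(hb$acceptor, 3L)
  expect_equal(hb$distance, 2.9)
  expect_equal(hb$angle, 180)

  # too distant
  expect_equal(nrow(hbonds(toy_model(hb_case(c(4.0, 0), c(0, 1.4))), 1:2, 3:4)),
               0L)
  # bent below the 120 degree donor-angle cutoff in both directions
  expect_equal(nrow(hbonds(toy_model(hb_case(c(-2.0, 1.4), c(1.4, 0))), 1:2, 3:4)),
               0L)
})

test_that("ligand contact tables count per-residue heme contacts", {
  prot <- data.frame(
    chain = "A", resno = 1:3, resid = "ALA", elety = "CA", element = "C",
    x = c(0, 50, 100), y = 0, z = 0, occupancy = 1, het = FALSE,
    stringsAsFactors = FALSE)
  hem <- data.frame(
    chain = "A", resno = 90L, resid = "HEM", elety = "FE", element = "FE",
    x = 2.5, y = 0, z = 0, occupancy = 1, het = TRUE,
    stringsAsFactors = FALSE)
  model <- toy_model(rbind(prot, hem))
  tab <- ligand_contact_table(model, "HEM")
  expect_equal(tab$HEM, c(1L, 0L, 0L))
  expect_equal(tab$any_contact, c(TRUE, FALSE, FALSE))
  expect_warning(t2 <- ligand_contact_table(model, c("HEM", "ASC")), "ASC")
  expect_equal(t2$ASC, c(0L, 0L, 0L))

  # tightening the cutoff never increases any count
  strict <- ligand_contact_table(model, "HEM", overlap_cutoff = -0.1)
  expect_true(all(strict$HEM <= tab$HEM))
})
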