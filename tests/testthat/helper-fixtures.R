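# Shared helpers: small alignments built in code, random records, and an
# independently coded residue-property table used as the conservation oracle.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_records <- function(n, len = 40L, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    protein_record(sprintf("seq%02d", i),
                   paste(sample(AA20, len, replace = TRUE), collapse = ""))
  })
}

# alignment whose rows are all equal to `row` except for named overrides
uniform_alignment <- function(row, n = 6L, overrides = list()) {
  rows <- rep(row, n)
  names(rows) <- sprintf("s%02d", seq_len(n))
  for (id in names(overrides)) rows[id] <- overrides[[id]]
  alignment_block(rows)
}

# place character `ch` at columns `cols` of an otherwise `bg` row
row_with <- function(len, cols, ch = "H", bg = "A") {
  chars <- rep(bg, len)
  chars[cols] <- ch
  paste(chars, collapse = "")
}

# Independent property-membership oracle (Livingstone & Barton assignments,
# keyed residue-first rather than property-first).
residue_properties <- function(aa) {
  props <- list(
    A = c("hydrophobic", "small", "tiny"),
    C = c("hydrophobic", "polar", "small"),
    D = c("polar", "small", "charged", "negative"),
    E = c("polar", "charged", "negative"),
    F = c("hydrophobic", "aromatic"),
    G = c("hydrophobic", "small", "tiny"),
    H = c("hydrophobic", "polar", "aromatic", "charged", "positive"),
    I = c("hydrophobic", "aliphatic"),
    K = c("hydrophobic", "polar", "charged", "positive"),
    L = c("hydrophobic", "aliphatic"),
    M = "hydrophobic",
    N = c("polar", "small"),
    P = c("small", "proline"),
    Q = "polar",
    R = c("polar", "charged", "positive"),
    S = c("polar", "small", "tiny"),
    T = c("hydrophobic", "polar", "small"),
    V = c("hydrophobic", "small", "aliphatic"),
    W = c("hydrophobic", "polar", "aromatic"),
    Y = c("hydrophobic", "polar", "aromatic")
  )
  props[[aa]]
}

amas_oracle <- function(residues, any_gap = FALSE) {
  residues <- unique(residues)
  if (length(residues) == 0L) return(0L)
  if (length(residues) == 1L && !any_gap) return(11L)
  all_props <- c("hydrophobic", "polar", "small", "tiny", "aliphatic",
                 "aromatic", "charged", "positive", "negative", "proline")
  per_res <- lapply(residues, residue_properties)
  agree <- sum(vapply(all_props, function(p) {
    has <- vapply(per_res, function(ps) p %in% ps, logical(1L))
    all(has) || !any(has)
  }, logical(1L)))
  max(if (any_gap) agree - 1L else agree, 0L)
}

# Independent quaternion (Horn 1987) absolute-orientation solver; returns
# the RMSD after optimally superposing b onto a.
quaternion_rmsd <- function(a, b) {
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2L, ca); b0 <- sweep(b, 2L, cb)
  m <- crossprod(b0, a0)
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  nmat <- matrix(c(
    sxx + syy + szz, syz - szy,        szx - sxz,        sxy - syx,
    syz - szy,       sxx - syy - szz,  sxy + syx,        szx + sxz,
    szx - sxz,       sxy + syx,       -sxx + syy - szz,  syz + szy,
    sxy - syx,       szx + sxz,        syz + szy,       -sxx - syy + szz
  ), 4L, 4L, byrow = TRUE)
  q <- eigen(nmat, symmetric = TRUE)$vectors[, 1L]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rot <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3L, 3L, byrow = TRUE)
  bf <- sweep(b0 %*% t(rot), 2L, ca, `+`)
  a1 <- sweep(a0, 2L, ca, `+`)
  sqrt(mean(rowSums((a1 - bf)^2)))
}

# Brute-force motif scan oracle: checks every offset position-by-position
# against its own pattern interpretation.
scan_oracle <- function(seq_str, pattern) {
  toks <- list()
  rest <- pattern
  while (nzchar(rest)) {
    if (startsWith(rest, "(")) {
      close <- regexpr(")", rest, fixed = TRUE)
      toks[[length(toks) + 1L]] <- strsplit(substr(rest, 2L, close - 1L), "/")[[1L]]
      rest <- substr(rest, close + 1L, nchar(rest))
    } else {
      ch <- substr(rest, 1L, 1L)
      toks[[length(toks) + 1L]] <- if (ch == "X") AA20 else ch
      rest <- substr(rest, 2L, nchar(rest))
    }
  }
  chars <- strsplit(seq_str, "")[[1L]]
  k <- length(toks)
  hits <- integer(0L)
  if (length(chars) >= k) {
    for (i in seq_len(length(chars) - k + 1L)) {
      ok <- TRUE
      for (j in seq_len(k)) {
        ch <- chars[i + j - 1L]
        allowed <- toks[[j]]
        # ambiguity codes only satisfy full-wildcard positions
        if (ch %in% c("X", "B", "Z", "U")) {
          if (length(allowed) != 20L) { ok <- FALSE; break }
        } else if (!(ch %in% allowed)) { ok <- FALSE; break }
      }
      if (ok) hits <- c(hits, i)
    }
  }
  hits
}
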