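# Residue alphabets and physicochemical lookup tables used across the package.

#' @keywords internal
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Ambiguity / non-standard codes accepted on input (match only wildcard motif
# positions, never a literal residue constraint).
#' @keywords internal
AA_AMBIGUOUS <- c("X", "B", "Z", "U")

#' @keywords internal
AA_ALLOWED <- c(AA_STANDARD, AA_AMBIGUOUS)

# Kyte & Doolittle (1982) hydropathy scale.
#' @keywords internal
KYTE_DOOLITTLE <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3
)

# Livingstone & Barton (1993) residue property assignments, as used by
# AMAS-style conservation scoring. Rows are the ten properties; a column
# conservation score counts properties on which all residues present agree
# (all share it, or none does).
#' @keywords internal
AA_PROPERTIES <- local({
  prop <- function(members) AA_STANDARD %in% members
  m <- rbind(
    hydrophobic = prop(c("I", "L", "V", "C", "A", "G", "M", "F", "Y", "W", "H", "K", "T")),
    polar       = prop(c("C", "D", "E", "H", "K", "N", "Q", "R", "S", "T", "W", "Y")),
    small       = prop(c("A", "C", "D", "G", "N", "P", "S", "T", "V")),
    tiny        = prop(c("A", "G", "S")),
    aliphatic   = prop(c("I", "L", "V")),
    aromatic    = prop(c("F", "H", "W", "Y")),
    charged     = prop(c("D", "E", "H", "K", "R")),
    positive    = prop(c("H", "K", "R")),
    negative    = prop(c("D", "E")),
    proline     = prop("P")
  )
  colnames(m) <- AA_STANDARD
  m
})

# Van der Waals radii (Angstrom), Bondi (1964) with common extensions for
# metals seen in heme/ligand groups. The table name is reported in contact
# output so counts are interpretable against the radii actually used.
#' @keywords internal
VDW_RADII <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
  FE = 2.00, ZN = 1.39, MG = 1.73, MN = 2.00, CU = 1.40, K = 2.75,
  CA = 2.31, `NA` = 2.27
)

#' @keywords internal
VDW_TABLE_NAME <- "bondi1964+metals"

# Fixed human reference column order used for best-match tie-breaking,
# matching the published identity table header.
#' @keywords internal
HUMAN_REF_ORDER <- c("Dcytb", "Lcytb", "CGcytb", "TScytb", "CYB561D1", "SDR2")
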