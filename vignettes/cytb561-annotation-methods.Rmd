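---
title: "Annotating cytochrome b561 families: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating cytochrome b561 families: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytb561anno)
```

# The scientific problem

Cytochrome b561 (cytb561) proteins transfer single electrons across a
membrane, typically from cytoplasmic ascorbate to a non-cytoplasmic
acceptor such as ferric iron or monodehydroascorbate. The family's
architecture is rigid in one respect only: a four-helix core holds two
b-type hemes coordinated by four universally conserved histidines — H1 and
H3 on the non-cytoplasmic side, H2 and H4 on the cytoplasmic side.
Everything else (loop lengths, termini, accessory domains) varies widely,
which makes absolute residue numbering useless across the family. This
package therefore treats the four histidines as a coordinate system:
residues are addressed as signed offsets from an anchor, e.g. `H1+20` or
`H3-5`, and all higher-level annotation (conservation catalogs, motif
registers, the ferric-reductase checklist) is expressed in those
coordinates.

# Anchor detection

`find_histidine_anchors()` works on a family alignment. Candidate columns
are those with a histidine fraction of at least `h_min` (default 0.95, not
1.0 — a single truncated or miscalled sequence should not abort detection).
Among all candidate quadruples whose consecutive spacings lie within
`[min_gap, max_gap]` = [15, 90] columns — the plausible range for helices
separated by short loops — the quadruple maximizing the summed histidine
fraction wins; ties break to the leftmost column vector. The defaults
tolerate families in which a functionally conserved histidine outside the
anchor set (such as the metal-binding His at H2+22 of the Dcytb-like
groups) is conserved in *part* of the family: as long as the family mixes
groups, that column stays below `h_min`. In a family consisting *only* of
sequences that share such an extra histidine, the problem is genuinely
ambiguous and the spacing constraints plus leftmost tie-break decide; users
analyzing single-group families should either lower-bound the spacing
accordingly or supply mixed alignments.

# The labeling convention for relative positions

A residue between two anchors has two possible labels (downstream `+` from
the earlier anchor, upstream `-` from the later one). The field's practice,
which this package reproduces in `to_relative()`, is not simply
"nearest anchor": positions such as `H1+20`, `H2+21`, `H2+22` and `H3+22`
are conventionally labeled downstream even when the upstream anchor is
nearer (e.g. the residue 20 after H1 is 16 before H2), while short upstream
offsets (`H2-7`, `H3-5`, `H3-2`) always win. The rule implemented is:
**use the downstream form unless the upstream offset is strictly less than
half the downstream offset**. This reproduces every published label we are
aware of; a plain nearest-anchor rule would relabel `H1+20` as `H2-16`.
`resolve_relpos()` is the inverse and round-trips exactly for every residue
and any labeling rule, because resolution uses the named anchor directly.

# Topology from hydropathy

Helix assignment uses sliding-window Kyte–Doolittle hydropathy
(`window = 19`, `threshold = 1.6`, `min_len = 15`): a sequence-only
surrogate for reading helices off experimental or predicted structures that
keeps the package free of structure downloads. A window average at center
*c* summarizes residues *c* ± 9, so runs of above-threshold centers are
widened by the half-window; when two widened neighbors collide, they are
split at the hydropathy minimum between their runs if that minimum dips
clearly below threshold (by 0.5), and merged otherwise. This handles the
family's short (8–18 residue) loops, which a 19-residue window cannot
resolve by thresholding alone. Sidedness then alternates from the
N-terminus (cytoplasmic for single-domain proteins, non-cytoplasmic for
CYBDOM-class proteins), and a structural sanity check requires each anchor
to sit nearer the face its heme occupies; violations yield an explicit
`undetermined` register rather than a silent guess. The register is
TM2–TM5 when H1 falls in the second segment and TM1–TM4 when it falls in
the first.

# Identity and classification

`percent_identity()` divides identical columns by columns where *both*
rows are non-gap. The convention behind the published identity table is
undocumented; this denominator was chosen because it is symmetric and
stable under span restriction, and recomputed identities should therefore
be read with a ±2-point tolerance. Pairwise values come either from global
Needleman–Wunsch alignments (BLOSUM62, gap open 10, extend 1, via
Biostrings) or from row pairs of a supplied family MSA
(`identity_matrix_from_alignment()`) — both protocols are provided because
the original analysis is ambiguous between them. Best-match ties break to
the fixed human column order Dcytb, Lcytb, CGcytb, TScytb, CYB561D1, SDR2.
The bundled fixture transcribes the published 54-row table; the bold
best-cell markers are deliberately *not* stored, so `best_match()` must
recompute them. `nj_tree()` wraps `ape::nj()` with validation and
negative-branch clamping; it is labeled NJ in its output and is a
clustering utility, not a reproduction of the study's maximum-likelihood
phylogeny.

# Conservation scoring

Three scorers cover the alignment-column statistics used in family
comparisons. The consensus logo reports the modal residue, `+` on ties and
`-` where the gap is modal. The AMAS-style score counts, over the ten
Livingstone–Barton physicochemical properties (hydrophobic, polar, small,
tiny, aliphatic, aromatic, charged, positive, negative, proline), how many
are decided unanimously by the residues present; an identical gap-free
column scores the maximal 11, and any gap removes the identity bonus and
one further point. Published "conservation score 8 or 9" thresholds should
be interpreted against *this* scorer — equivalence with any specific
viewer's implementation is not claimed, only monotone agreement on
clear-cut columns (the score provably never rises when a column
diversifies). The entropy score is the unweighted natural-log column
entropy over non-gap residues, standardized so higher means more conserved,
with a display clamp at ±1.5 matching common structure-coloring gradients.

# Motifs and the ferric-reductase checklist

Motif patterns combine literals, `X` wildcards and residue classes like
`(D/E)`. Ambiguity codes in a *sequence* (X/B/Z/U) satisfy only wildcard
positions — an unknown residue never proves a literal constraint — and all
overlapping matches are reported. Region constraints are strict:
dileucine signals are scanned only downstream of the last transmembrane
segment, and the `KXXXXKXH` scan window is the H2→H3 inter-anchor interval
(a sequence-only stand-in for the non-cytoplasmic loop, consistent with the
motif's histidine at H3−5; whether the original loop definition was
narrower is unknowable from sequence alone). The DOMON heme-ligand finder
requires a *unique* `SXDXXMGXD` match in the given span and, when a DOMON
alignment is supplied, takes the partner histidine from the first
downstream column that is ≥90% His.

The checklist classes are the observed substitution sets of the
ferric-reductase catalog, anchored on duodenal cytochrome b561: the four
activity-critical items (H2+22 His; H2+21 Asn or its conservative Ser;
H3−3 Tyr; H4+25 aromatic) and supporting heme/ascorbate items
(basic residues at H2−7, H2−3, H4−7 and H1+20; polar positioning residues
at H3+14, H3−2, H3−5; the H3+2 tryptophan; small residues at H3+4, H3+18,
H4+4, H4+18). Items whose offset leaves the sequence are reported
`unresolvable`, not failed — short CYBDOM homologous regions legitimately
truncate the catalog. Users may override the classes via the `catalog`
argument.

# Structure geometry

Superposition is a standard Kabsch least-squares fit (proper rotation
enforced); `prune_superpose()` refits after dropping pairs deviating more
than 2 Å until stable, reporting RMSD both over retained pairs and over all
pairs under the final transform — mirroring the "pruned pairs / all pairs"
reporting convention of interactive structure viewers. Contacts use van
der Waals overlap `r_a + r_b − d ≥ −0.4` Å with Bondi (1964) radii (the
table is named in every output, because contact counts are radii-table
sensitive; replication of any specific viewer's counts is approximate).
Hydrogen bonds use a heavy-atom criterion (donor–acceptor N/O distance
≤ 3.5 Å, antecedent–donor–acceptor angle ≥ 120°) with no hydrogen
placement: predicted models and moderate-resolution crystal structures make
hydrogen inference noise, so the geometric criterion is reproduced at the
heavy-atom level and both thresholds are exposed.

# The synthetic family generator

`simulate_family()` exists so that every pipeline stage can be tested
against known ground truth. Its defaults *are* the study-like conditions:
five groups (11 + 8 Dcytb-like, 10 CYBDOM-class, 7 + 18 less-conserved)
with inter-anchor spacings 36/34/39 — the register that places the anchors
at residues 50/86/120/159 in the single-domain template — the
ferric-reductase catalog planted in the Dcytb-like groups, the `KXXXXKXH`
motif in exactly 6 of the 7 TScytb-like sequences, `EDXXLL` in every
CG1275-like tail, the `SXDXXMGXD` pocket in every CYBDOM N-terminal region,
double cysteines in both Nemy-like cytoplasmic core loops, a 20% per-site
substitution rate at unconstrained sites and a 10% per-loop indel rate.
Substitutions are uniform over the 19 alternatives rather than
matrix-weighted, so expected identity is the closed form 1 − *m* and the
divergence calibration is exactly testable. Indels are confined to loops
and additionally never separate an anchor from a feature whose coordinate
is anchored to it, so planted histidine-relative positions survive exactly;
helices are 21 residues from a strongly hydrophobic pool and loops lean
strongly hydrophilic so that helix/loop contrast survives the polar
functional residues planted inside helices.

What the generator does *not* emulate: phylogenetically structured
mutation (sequences are i.i.d. around the template), substitution-matrix
biases, compensatory covariation, and the compositional quirks of real
membrane proteins. Passing recovery tests therefore demonstrates
correctness of the annotation logic under controlled conditions, not
performance on real proteomes. `synthetic_dcytb()` builds a clearly
labeled *synthetic* stand-in for the duodenal cytochrome b561 reference:
the residues known to matter are planted at their reported positions on a
generated scaffold; it is not the natural sequence, and tests that use it
verify coordinate arithmetic and checklist logic, not biology.

# Problem sizes and numerical choices

The shipped tests and the acceptance script use 50 seeded replicates for
anchor recovery, 20 seeds for the divergence calibration, 40 sequences for
the motif-recall binomial check, 1000 random sequences per motif for
scanner/oracle equivalence, all 1140 three-residue columns for the
conservation scorer oracle, and 80–120-point clouds for the geometry
oracles (quaternion equivalence at 1e−9, rigid-transform invariance at
1e−9, exact planted-outlier recovery). These sizes give tight binomial
intervals and exhaustive small-case coverage while keeping a full run in
well under a minute. Floating-point tie-breaks in anchor selection use a
1e−12 tolerance on summed fractions; NJ branch lengths below zero are
clamped with a warning; degenerate (collinear) point sets are rejected
rather than fitted.

# Known limitations

- Hydropathy topology is a heuristic: heavily mutated or unusually polar
  helices can merge or vanish, in which case the register is reported
  `undetermined` and downstream loop-based operations decline to run.
- The identity convention is one defensible choice among several;
  cross-tool comparisons should allow ±2 percentage points.
- The checklist encodes observed substitution sets, not biochemical proof;
  a `core4` pass is a hypothesis generator, not an activity assay.
- Contact and hydrogen-bond counts depend on the radii table and
  thresholds; they reproduce the criterion, not any specific program's
  output byte-for-byte.
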