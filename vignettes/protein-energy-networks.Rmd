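---
title: "Protein energy networks: model, family alignment and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protein energy networks: model, family alignment and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(penet)
```

## The model

A protein energy network (PEN) keeps the residue-level graph abstraction
of a contact map but weights each residue pair by physics rather than
geometry. For residues *i* and *j* the edge weight is the non-bonded
interaction energy

$$E_{ij} \;=\; \sum_{p \in i}\sum_{q \in j}
\left[\; \frac{f\,q_p q_q}{\varepsilon_r\, r_{pq}}
\;+\; 4\epsilon_{pq}\!\left(\Big(\tfrac{\sigma_{pq}}{r_{pq}}\Big)^{12}
- \Big(\tfrac{\sigma_{pq}}{r_{pq}}\Big)^{6}\right)\right]$$

summed over all inter-residue atom pairs, with $f = 138.935485$
kJ mol$^{-1}$ nm e$^{-2}$ the molecular-mechanics Coulomb constant,
and averaged arithmetically (equal weights) over the frames of a
conformational ensemble — a multi-MODEL PDB, an NMR bundle, or a short
simulation sampled at regular intervals. The assumptions inherited from
this form are the usual fixed-charge force-field ones: pairwise
additivity, no polarization, no solvent, no bonded terms. Self pairs and
sequential neighbours ($|i-j| \le 1$ within one chain) are excluded
because their energies are dominated by covalent geometry rather than
fold-defining packing; inter-chain pairs are never excluded. An `ljPEN`
keeps only the Lennard-Jones term and so isolates the van der Waals
(hydrophobic-packing) skeleton from the electrostatics.

Thresholding at a maximum energy cutoff *e* yields the unweighted
`PEN_e`: an edge exists where $E_{ij} \le e$. Since favourable energies
are negative, "at or below" means "at least as favourable", and edge
sets are nested as *e* rises — the property behind the sigmoidal
largest-cluster (LC) transition: very negative cutoffs leave a few
strong, mostly electrostatic contacts; relaxing the cutoff accretes
weaker van der Waals edges until one component spans the protein.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `dielectric` | 1 | – | raw vacuum molecular-mechanics potentials; screening models are the user's choice |
| `combiningRule` | Lorentz–Berthelot | – | arithmetic $\sigma$, geometric $\epsilon$; the most common convention, `"geometric"` available |
| `distanceCutoff` | none | nm | all atom pairs summed; a cutoff is an optional speed device, not part of the model |
| cutoff `e` | user-set | kJ/mol | around −15 to −20 selects the electrostatic (pre-transition) regime, around −7 to −10 the van der Waals regime |
| cluster `minSize` | 3 | nodes | isolated pairwise interactions are not clusters |
| single-protein hub degree | 4 | edges | free parameter; family hubs are fixed at degree ≥ 3 |
| family hub `memberFraction` | 0.7 | – | a hub is conserved when ≥ 70 % of members are hubs at the equivalent position |
| `ccThreshold` | user-set | – | inclusive: `cc = 1.0` selects edges present in *every* member |
| virtual-node sentinel | +100 | kJ/mol | stored for fidelity; edge exclusion at virtual nodes is also enforced structurally |
| SS `denominator` | union (Jaccard) | – | alternatives `min`, `mean` exposed as flags |
| distance | $D = 1 - SS$ | – | `neglog` variant available, guarded at $SS = 0$ |
| `linkage` | average (UPGMA) | – | `single`/`complete` available |

The force field itself is deliberately pluggable: a TSV of per-atom
partial charges and LJ $\sigma/\epsilon$ (`res_name`, `atom_name`,
`charge_e`, `sigma_nm`, `epsilon_kjmol`). Absolute energies are
parameter-set-dependent, so the package's own guarantees rest on analytic
anchors ($V_{LJ}(\sigma) = 0$, $V_{LJ}(2^{1/6}\sigma) = -\epsilon$, the
Coulomb constant at 1 nm) and on relative/threshold behaviour, not on
reproducing any particular published energy table.

## Family alignment and commonality

Members of a structural family are aligned by an external structural
aligner (e.g. MUSTANG); the package consumes the aligned FASTA (MSSA) and
never recomputes superpositions. Each member's `PEN_e` is remapped onto
the L alignment columns; columns that are gaps for a member become
*virtual nodes*. Two conventions coexist deliberately: the remapped
*energy* matrix carries the +100 kJ/mol sentinel at virtual pairs (so any
realistic negative cutoff rejects them), while the remapped *network*
enforces zero degree at virtual nodes structurally. The commonality
coefficient of an aligned edge is $cc_{ij} = X_{ij}/M$ with $X$ the
number of members possessing the edge. A member gapped at either column
cannot possess the edge: it contributes 0 to $X$ while $M$ stays the
family size — the alternative (shrinking $M$ per edge) would let a
position conserved in two of ten members masquerade as fully conserved.
All alignment columns are carried regardless of gap content; no column
pruning.

Per-column residue conservation uses a plain entropy index: the raw score
is $\sum_a p_a \ln p_a$ (negative Shannon entropy, nats) over the
amino-acid frequencies among non-gap symbols, so a fully conserved column
scores 0 and maximal diversity $-\ln 20$. Scores are z-normalized by the
mean and *population* SD across defined columns (the sample convention is
available); all-gap columns are undefined and excluded. Sequences are
counted unweighted — families are assumed pre-culled for redundancy
(< 30 % identity), which is exactly the regime the method targets.
Substitution-matrix-weighted and window-smoothed variants of the entropy
index exist in the wider literature; only the plain-entropy form is
implemented here.

## Interaction-conservation phylogeny

For members *a*, *b* the conserved-edge matrix marks column pairs whose
edge exists in both remapped networks; the similarity score $SS_{ab}$ is
the conserved count divided by the union of the two edge sets (a Jaccard
index on edge sets), and $D = 1 - SS$ feeds average-linkage (UPGMA)
clustering, serialized as Newick with branch lengths. "Similar
interaction" is binary by default (joint presence at cutoff *e*); an
energy mode additionally requires $|E^a_{ij} - E^b_{ij}| \le$ `tol`.
Pairwise comparisons reuse the family MSSA projected onto the two
members rather than recomputing pairwise structural alignments — a
documented divergence that trades a little pairwise accuracy for
consistency of the column space across all pairs. Members are sorted
lexicographically before clustering so the tree is invariant to input
order; two members with empty edge sets get $SS = 1$ (identical
emptiness) with a warning rather than an undefined 0/0.

## The synthetic generator

`makeFamily()` emulates the statistical skeleton of a structural family:
a planted set of conserved edges present in every member (energies
U(−30, −15) kJ/mol, the strongly favourable regime where electrostatics
dominate), optional clade-specific edge pools (same range) shared within
but not across clades, per-member private noise edges (U(−14, −8), the
moderately favourable van der Waals-like regime) and a background of
non-interactions (U(−5, 0)). The three ranges are disjoint by
construction, so a cutoff of −10 kJ/mol cleanly separates planted edges
(always kept) from background (always rejected) while noise edges
straddle it. Three structural guarantees keep the truth tables exact:

* gaps are placed only at columns untouched by planted or clade edges;
* a member's gap pattern is rejection-sampled so that deleting its gap
  columns never collapses a planted edge onto a sequential-neighbour
  residue pair (which the energy-matrix convention would silently drop);
* noise edges are drawn disjointly across members, so each is genuinely
  private — no chance coincidence can push a noise edge's cc above 1/M.

`privateEdgeRate` is the Poisson mean of the per-member noise count, and
identical seeds give byte-identical files. Letters at planted-edge
columns are conserved across members (mimicking conserved residues at
conserved interactions); other columns are uniform random letters.

What the generator does **not** emulate: real geometry (no coordinates
are consistent with the matrices), force-field detail, correlated noise
between related members, insertion-block gap structure, or any relation
between sequence letters and energies. Passing tests therefore
demonstrate that the algorithms recover what the model defines —
commonality, conservation, clade structure — not that any particular
protein family behaves this way. `makeToyStructure()` covers the other
end: two-particle and 4+-residue linear-chain systems whose energies are
hand-computable, for validating the energy model itself.

## Numerical choices and degenerate inputs

* Coordinates are Å in all structure inputs and converted to nm
  internally; energies are always kJ/mol.
* Coincident atoms (r = 0) are a hard error naming the atoms, not an
  infinity.
* Unparameterized hydrogens are dropped with a warning (heavy-atom
  computation proceeds); any other unparameterized atom is an error
  listing the residue/atom names.
* In PDB input the first altloc is kept; multi-MODEL files are ensemble
  frames.
* The LC of an edgeless network is 0 (components are counted only when
  they carry an edge); the LC-profile midpoint is the first grid crossing
  of 0.5, linearly interpolated.
* cc and fraction comparisons use a 1e-12 slack so `cc = 1.0` is immune
  to floating-point representation of X/M.
* Interface classification precedence: a loop endpoint dominates, then
  mixed helix/strand, then helix–helix, then strand–strand split into
  long-range (strand-index difference ≥ 2) vs contiguous; an optional
  wrap-around flag makes the first and last strands adjacent, since
  closed beta barrels have no first strand.
* Deterministic orderings break ties lexicographically (cluster members,
  column labels `c001…`, member order before clustering).

## Problem sizes

The shipped test-suite and benchmark sizes are desk-scale by design:
random matrices up to 60 residues, families of 2–8 members, 100-replicate
property checks, and a 100-replicate two-clade phylogeny benchmark
(M = 6, L = 60, 8 shared + 40 clade edges, noise rate 1, gap rate 0.05 —
chosen so within-clade edge overlap stays ≥ 0.8 and between-clade ≤ 0.3).
The algorithms themselves scale to real domains (hundreds of residues,
tens of members); the energy builder is vectorized over atom pairs and
the optional distance cutoff exists purely to curb its quadratic cost.

## Known limitations

* Absolute energies depend entirely on the user-supplied force field;
  the bundled table is a toy set for fixtures, not a physical model.
* No dynamics: the package consumes ensembles, it does not generate
  them, and a single crystal structure gives a single-frame "average".
* The MSSA is trusted as given; alignment errors propagate directly into
  commonality and conservation scores.
* No bootstrap or other support values on the cladogram, and no
  tree-comparison metrics beyond leaf-set checks.
* Secondary-structure labels are consumed from file (DSSP-style
  H/E/C + strand index), not computed.
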