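---
title: "Backbone-dependent 3D hydropathic interaction maps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Backbone-dependent 3D hydropathic interaction maps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

hydromaps deconstructs a protein (or protein--lipid) structure into
residue-level, backbone-conformation-binned three-dimensional maps of the
hydropathic interactions each sidechain makes with its environment. The
premise is that a residue in a given backbone conformation has a
*hydropathic valence* -- a characteristic constellation of favorable and
unfavorable, hydrophobic and polar contacts -- and that after clustering,
a modest library of average maps per residue type and conformation captures
most of what the structure database has to say about that residue's
interactions. For membrane proteins the same machinery, run with and without
the lipid partners, isolates the residue--lipid interactions that are hard
to observe experimentally.

## Pair scoring

Atom pairs are scored with a logP-based (HINT-style) function

$$ b_{ij} = a_i S_i \, a_j S_j \; T_{ij} \, e^{-r_{ij}} $$

where $a_i$ is a sign-carrying hydrophobic atom constant (positive for
carbons and attached hydrogens, negative for N/O/S, most negative for
formal-charge bearing atoms), $S_i \in [0,1]$ is the Shrake--Rupley exposed
fraction of the atom's solvent sphere (probe 1.4 Å, Bondi radii, 960
deterministic sphere points), $r_{ij}$ is the interatomic distance in Å
(cutoff 8 Å), and $T_{ij} = -1$ for like-polar pairs (acid--acid,
base--base), $+1$ otherwise. Each pair falls in exactly one class:

* both hydrophobic → **Hyd(+)** (favorable hydrophobic),
* hydrophobic × polar → **Hyd(−)** (desolvation; forced negative),
* acid--base or any amphoteric polar pair → **Pol(+)**,
* acid--acid / base--base → **Pol(−)**.

The atom-constant table ships as an editable TSV
(`inst/extdata/hint_atom_constants.tsv`). Magnitudes are calibration
constants chosen for sign- and rank-consistency with the Hansch--Leo
fragment conventions, not fitted quantities; every package result that we
test is invariant to a global rescaling of the table. Hydrogens inherit
their constants from the parent heavy element, which keeps the table small
and makes user edits safe. The Lennard-Jones correction of the full HINT
force field is deliberately omitted; the class semantics and exponential
distance attenuation are what the downstream maps consume. Lipids (DPPC)
are treated united-atom -- tail carbons carry slightly larger constants in
lieu of explicit hydrogens -- consistent with their provenance from
coarse-grain simulation snapshots.

## Ionization states

ASP, CYS, GLU and HIS are modeled at a per-type pH50 (the pH that splits
the population evenly): soluble set 3.3449 / 9.5814 / 4.2240 / 5.1743,
membrane set 3.9331 / 9.4506 / 4.2021 / 5.4206. For each residue the
protonation variants are scored against the environment (protonated --XH
hydrogens scanned in 30° steps; HIS as the two neutral tautomers plus the
cation, each with the imidazole as built and flipped 180° about CB--CG,
six variants in total) and corrected by
$\mathrm{raw} - k \cdot 2.303\,R\,T\,\max(0, \sigma (\mathrm{pH} - pK_a))$
with $\sigma = +1$ for protonated and $-1$ for deprotonated states,
$k = 515$ score units per kcal/mol and $T = 298.15$ K; ties go to the
deprotonated form. Because the correction is linear in pH with opposite
signs for the two states, the selected state switches exactly once along a
pH sweep -- the monotone titration the test suite checks. Nominal pKa
values (ASP 3.71, GLU 4.15, CYS 8.55, HIS 6.04) are model-compound values
and configurable.

## Backbone bins and the canonical frame

The Ramachandran plane is divided into sixty-four 45°×45° *chess squares*
`a1`..`h8` (column letter bins φ, row digit bins ψ, both ascending from
−180°, lower-left to upper-right). Sidechain conformations subdivide the
square into *parses*: contiguous 120° χ1 bins `.60` [0°,120°), `.180`
[120°,240°), `.300` [240°,360°); ARG/GLN/GLU/LYS additionally by χ2 (nine
two-angle parses); PRO into `.30p`/`.30m`; ALA/GLY/VAL unparsed. The
contiguous 120° definition is used rather than a 60°-wide "60 ± 30°"
reading, since parses must cover every conformation. One genuine ambiguity
remains: the source convention places the ideal α-helix at the `c5`/`c3`
boundary depending on the row registration, which cannot be recovered from
the available description; the binning convention above is the default and
a registration offset (`phi_offset`/`psi_offset`) is exposed for users who
need a different board alignment. All package results are internally
consistent under either registration.

Maps are computed in a canonical residue frame: CA at the origin, CA→CB
along +z, CA→HA in the yz-plane with positive y. For GLY the pro-S α
hydrogen (the one nearest the position an L-residue's CB would occupy)
stands in for CB, and GLY maps cover the entire residue rather than a
sidechain.

## Map deposition

Each residue's four-class map set lives on a cubic 0.5 Å grid centred on
CA, sized from the residue type's extended-conformer reach plus 5 Å of
padding per dimension. Every scored pair deposits its value at the
frame-transformed pair midpoint as an isotropic Gaussian (σ = 0.5 Å,
truncated at 2σ) normalized over its in-box stencil so the deposited grid
sum equals the pair value exactly. This conservation is what makes the
*interaction character* -- the four per-class grid sums -- equal the
per-class pair-score sums, and it holds to 1e−6 relative in the property
suite. Pairs whose kernel has no in-box node are counted as clipped and a
warning fires if clipped mass exceeds 1% of the total. Characters can be
normalized by the residue type's random-coil reference SASA (×100/area);
CYX uses 153.5 Ų (150% of CYS) and GLY its full-residue 87.2 Ų.

## Clustering

Within each (type, square, parse) bin, map similarity is the per-class
Hodgkin index $H_c = 2\sum f_a f_b / (\sum f_a^2 + \sum f_b^2)$ combined
across the four classes with weights proportional to each class's joint
norm: bounded in [−1, 1], 1 at identity, −1 for a negated map, 0 for
disjoint support. Rows of the similarity matrix are the k-means feature
vectors (the matrix, not the raw grids, is clustered). k is chosen by the
gap statistic with 50 uniform-box reference sets. We use the dominant
gap-jump criterion guarded by a 1-SE significance check rather than the
classical smallest-k 1-SE stopping rule: with tight, well-separated map
clusters the gap curve keeps creeping upward past the true k by more than
its (very small) simulation error, and the stopping rule over-clusters;
the jump criterion recovers planted 2/3/5-cluster populations reliably,
which is the property the test suite enforces. Bins with fewer than five
maps are averaged into a pseudo 1-cluster instead of being clustered.

Members whose distance to their assigned centroid exceeds the pooled
mean + 3 sd of within-cluster distances are split out as singletons
(k-means cannot produce singleton clusters by itself; this backfills
them). Cluster averages weight each member by
$w_i = \exp(-d_i^2 / 2\sigma_w^2)$ with $\sigma_w$ the median centroid
distance (ε-floored when all distances vanish), normalized to sum 1. Each
cluster is named by its exemplar's ordinal in the bin; the exemplar is the
member most similar to the cluster's average map, which makes "the
exemplar best represents the average" an invariant rather than a tendency.

## SASA, LASA and membrane environments

Residues of a membrane protein are classified from two annotation
sidecars: the average phosphate planes (upper/lower z) and a per-residue
pore-lining flag. A residue with all of N, CA, C strictly between the
planes is in the membrane region -- core-facing (mC) if pore-lining,
lipid-facing (mL) otherwise; everything else is in the soluble domain
(mS). Lipid-facing residues are scored twice: with lipid partners (mL) and
without (mN); the mL − mN difference map isolates the residue--lipid
interactions. Lipids beyond 6 Å (atom--atom minimum, boundary inclusive)
of any protein atom are trimmed first.

Sidechain solvent-accessible areas come from the same Shrake--Rupley
machinery. A residue's accessible area is labeled LASA (lipid-accessible)
when the lipid share of its absolute interaction-score sum exceeds 0.1,
strictly; otherwise SASA. The label is binary per residue -- the
alternative pro-rata split by lipid ratio is defensible but the
classification reading is used, and type-level tables then report both
columns because members differ.

## Composite and score grids

For a whole protein (or a residue subset) a protein-frame grid is built
from the selection's bounding box ±5 Å at 0.5 Å spacing. Each residue's
canonical alignment is "unapplied": protein-grid points are carried into
the residue frame, and points inside the residue's standard box receive
eight enclosing node indices and trilinear weights (sub-cube volumes over
the 0.125 ų cell). Weight sums are exactly 1 at every relevant point.
Composite maps accumulate the interpolated cluster-average maps per class;
by linearity the mL-assignment composite minus the mN-assignment composite
equals the composite of the difference maps. Mass is conserved exactly for
translation-aligned frames when deposits sit in the box interior (the
boundary slab lacks a complete dual interpolation cell -- irrelevant in
practice because the 5 Å padding keeps real deposits interior); under
rotation the dual trilinear sum is only approximately one, so conservation
there is approximate by nature.

The score grid offers two contracts. The additive mode is the literal
reading: each point holds the sum of interpolated values and
$S_{model}$ is the grand total; it is separable, so its optimum is the
per-residue argmax. Because "matching map patterns" implies inter-residue
coupling that a pure sum cannot express, an optional overlap mode adds
$\tfrac12[(\sum_i h_i)^2 - \sum_i h_i^2]$ per point (and likewise for the
net polar field): same-sign co-location between different residues is
rewarded, opposing-sign co-location penalized. Neither reading is asserted
as the original; additive is the default. The assignment optimizer
enumerates exhaustively up to 10^6 models and otherwise runs seeded
steepest-ascent coordinate search with random restarts; the worked
arithmetic 6×12×12×12×4 = 41,472 candidate models is reproduced by
`countModels()`.

# The synthetic data generator

`makeMembraneFixture()` builds the package's study condition: an ideal
α-helical bundle (default seven antiparallel helices of 28 residues,
~196 residues) spanning a 30 Å bilayer (planes at z = ±15 Å), with ~40
DPPC-like lipids -- polar head beads (choline N, phosphate P + four
oxygens, glycerol/ester carbons) at the planes and two eight-carbon
hydrophobic tails pointing to the membrane centre -- packed around the
bundle in two leaflets. Helices are built at φ = −57°, ψ = −50° with ±4°
torsion jitter (kept clear of the 45° bin edges so one helix populates a
single chess square), sidechains at their canonical rotamers with ±8° χ
jitter, and 0.03 Å coordinate noise so no two maps are exactly degenerate.
Residue types default to orientation-dependent sampling: lipid-facing
positions from {LEU, ILE, VAL, PHE, ALA}, pore-facing from {SER, THR,
GLY, ASP, ALA}. Pore flags mark inward-facing in-membrane residues; the
phosphate-surface sidecar and the planes JSON carry the same leaflet
information in the two accepted formats. Everything is deterministic per
seed, byte-identical across runs.

What the generator does *not* emulate: crystallographic waters, sidechain
packing optimization (rotamers are ideal, not energy-relaxed), loops and
sheets (only helical squares are populated), lipid conformational
diversity, and experimental noise models. Passing tests therefore
demonstrate the correctness and internal consistency of the machinery --
conservation, invariance, classification rules, clustering behaviour --
not database-scale biological statistics: the published per-cluster tables
derive from thousands of real structures and are out of desk scope.

# Problem sizes and numerical choices

The test suite and acceptance script run the full pipeline on the default
fixture (~196 residues, ~40 lipids, both mL and mN map sets, clustering,
composites), which completes in about a minute on one CPU; unit and
property tests use two-residue toys, three-helix mini-bundles (54
residues) and 9³-node synthetic map populations. Deterministic seeds are
threaded through every stochastic step (jitter, k-means starts, gap
references, optimizer restarts). Key numerical conventions: angles live in
[−180°, 180°) and χ bins in [0°, 360°); the dihedral is IUPAC-signed and
invariant under full reversal of the four atoms; lipid trimming is
inclusive at 6.0 Å; "between the planes" is strict; the LASA rule is
strict at 0.1; altloc ties resolve to conformer A; ionization ties resolve
to the deprotonated state; clustering ties (exemplar choice) resolve to
the lowest ordinal.

# Known limitations

* Atom-constant magnitudes are calibration constants; absolute score
  units are not comparable to any published force-field output.
* Hydrogen placement is geometric (no minimization); rotatable protons
  are placed anti except where the ionization scan optimizes them.
* The HIS variant set has six members (tautomers × ring flip); extending
  to other enumerations is a documented hook.
* The overlap score is one reasonable formalization of pattern matching;
  the additive score is the literal one. Neither is claimed to reproduce
  any external implementation.
* GETAREA-style analytic areas are approximated by Shrake--Rupley
  sampling (960 points), accurate to well under 2% on the fixtures the
  suite checks.
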