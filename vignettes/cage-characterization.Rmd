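---
title: "Characterizing hollow protein cage assemblies with cagekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing hollow protein cage assemblies with cagekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cagekit)
```

## The problem

Large hollow protein assemblies — carboxysomes, vaults, chaperonins, and the
recently described megadalton CAGE complexes of microbial eukaryotes and
gram-negative bacteria — are characterized by a recurring set of desk-scale
computations once a structural model exists: parsing the monomer into
structural domains from predictor confidence, validating the assembly against
cross-linking mass-spectrometry (XL/MS) distance restraints, measuring the
enclosed cavity and its openings, mapping interaction partners to the
interior or exterior face, inferring the oligomeric copy number from
size-exclusion chromatography (SEC), and placing homologs on a distance tree.
cagekit packages these steps as tested, composable functions, together with
seeded synthetic-data generators so that every stage can be exercised against
machine-readable ground truth without any external download.

The running example throughout is a homotetramer of a ~2,200-residue monomer
(the *Tetrahymena* CAGE1 protein is 2,216 residues and 258 kDa, so the
tetramer comprises 8,864 residues and ~1 MDa), assembling into a flattened
hollow ellipsoid roughly 22 nm long and 12–16 nm across with an 18 × 8 × 8 nm
cavity of roughly 600 nm³.

## Domain segmentation from predicted aligned error

A predictor's PAE matrix gives, for every residue pair (i, j), the expected
positional error of residue j when the prediction is aligned on residue i.
Low error in either direction indicates that the pair is rigidly placed, so
we fold the (generally asymmetric) matrix into symmetric confidence weights

$$w(i,j) = \max\!\left(0,\; 1 - \frac{\min(\mathrm{PAE}_{ij},
\mathrm{PAE}_{ji})}{c}\right),$$

with cutoff $c = 12$ Å by default: pairs with 12 Å or more of mutual
uncertainty carry no signal. Domains are then communities of the weighted
residue graph. We use the Leiden algorithm with the modularity objective
(resolution 1 by default) under a fixed internal random seed, which makes
the output deterministic; Leiden is the de-facto standard for this task and
scales comfortably to chains of several thousand residues, where a naive
greedy agglomeration written in R would not. Three sequence-aware cleanup
passes follow, in order:

1. contiguous runs shorter than `min_segment` (default 5 residues, the scale
   of the shortest segments observed in real multi-segment domains) are
   absorbed into the better-connected flanking domain;
2. domains smaller than `min_domain` (default 40 residues) are merged into
   the cluster they are most strongly connected to, with ties broken toward
   the cluster containing the lowest residue index;
3. residues whose mean weight to their own domain falls below
   `linker_threshold` (default 0.2) are relabeled *linker*.

Linkers are an explicit label because real cage proteins have substantial
inter-domain linker content. Because the run-absorption pass is deliberately
sequence-aware, full permutation invariance holds for the community step
(`min_segment = 1`); with cleanup enabled the output is invariant to domain
relabeling but not to residue shuffling, which has no physical meaning for a
chain anyway.

Note that the published 15-domain parsing of CAGE1 combined PAE boundaries
with visual inspection of the structure; it is therefore shipped as a
reference *fixture* (`cage1_domains()`), not claimed as an algorithmic
reproduction target. On synthetic PAE matrices shaped on that fixture
(block means 4 Å within / 25 Å between, 2 Å noise, the 31.75 Å ceiling used
by public predictor databases), `pae_domains()` recovers the planted
partition with pair agreement above 0.99; the residual disagreement is the
19-residue three-segment domain, which falls below `min_domain` and is
deliberately merged. Agreement is measured by the Rand index over residue
pairs, with linker residues treated as singletons so that two linkers never
count as "same domain". As printed, domains 10 and 11 of the reference
parsing overlap at residue 1244; the package resolves such overlaps
first-come (the lower domain id keeps the residue) with a warning.

## Cross-link validation on homo-oligomers

A cleavable amine-reactive cross-linker such as DSSO constrains linked
residues to about 35 Å Cα–Cα in the assembled structure; the restraint is
inclusive (a link at exactly 35.0 Å is satisfied). In a homo-oligomer the
spectrum cannot tell which chain copy each peptide came from, so geometry
arbitrates: `assign_link()` takes the minimum over all same-chain
assignments as the intra-chain candidate and the minimum over ordered chain
pairs as the inter-chain candidate, classifies by the smaller, and demotes
the call to *ambiguous* when the two candidates lie within `tie_margin`
(default 1 Å) of each other. Links whose residues cannot be placed are
reported as unmappable, never dropped. The implementation is checked against
an exhaustive enumeration oracle over all chain pairs on synthetic
tetramers, and is invariant to chain relabeling and rigid-body motion.

`partner_face()` combines partner cross-links with the cavity module's
surface labels to call each partner protein *interior*, *exterior*, or
*ambiguous* — ambiguous being the honest answer when a partner (as reported
for actin) touches both faces.

## Cavity geometry

The model is discretized on a cubic lattice (default 2 Å voxels) with two
occupancy fields: voxels within the atom radius of any atom (default 2 Å,
the pseudo-atom radius class of the synthetic shells), and voxels within
atom radius + probe radius (default 5 Å). The complement of the dilated
field is the set of positions a spherical probe's *center* can occupy.
Flood-filling it 6-connected from the grid boundary separates outside probe
positions from enclosed ones; the probe cannot pass an opening narrower
than its own diameter, which is exactly what keeps a fenestrated cage
"closed". Each side is then re-dilated by the probe radius to recover the
space the probe body sweeps: the swept outside is the exterior mask, and
the largest enclosed swept component is *the* cavity (others are minor
voids). This probe-sweep construction is what makes the measurement robust
for shells assembled from discrete atoms: atomic-scale packing gaps inside
the wall are unreachable by the probe and therefore never counted, whereas
a naive "empty and not outside" rule would leak into them.

Cavity volume is the voxel count times the voxel volume, reported in nm³
(1 nm³ = 1000 Å³). Ellipsoid axes come from the principal components of the
cavity voxel centers via the uniform-solid-ellipsoid moment relation
(full axis $= 2\sqrt{5\lambda_k}$); this assumption is stated in the report,
and the closed form $V = (\pi/6)abc$ is exposed directly as
`ellipsoid_volume()` (18 × 8 × 8 nm gives 603.2 nm³, which the summary
line rounds to "approximately 600 nm³"). Cavities under 10 voxels are
flagged unreliable. On hollow-sphere fixtures the measured volume is within
2% of the closed form at 2 Å voxels and the error decreases at 1 Å;
rigid-body motion changes results only by voxelization jitter (tested at
5%).

Openings are passages wider than atomic packing but narrower than the
probe. They are detected by eroding the empty space by a clearance margin
(voxels within atom radius + 2 Å of an atom are discarded), grouping the
remaining channel voxels 26-connected outside the cavity and exterior
masks, and keeping components in contact with both; the area is the channel
voxel count × voxel², in nm². Slits below roughly twice the clearance
(~8 Å for the defaults) are treated as atomic-scale and not counted; slits
wider than twice the probe diameter break enclosure altogether, at which
point there is no cavity to report. Surface residues are labeled by the
nearest empty voxel within `reach_radius` (8 Å): interior if it belongs to
the cavity, exterior if to the outside, buried when neither is reachable or
both are equidistant within 2 Å.

## SEC calibration and stoichiometry

Within a gel-filtration column's resolving range, elution volume is linear
in log molecular weight. `fit_calibration()` regresses
$\log_{10}(\mathrm{MW})$ directly on elution volume — column void and total
volumes are rarely reported, so a $K_{av}$ transform is not assumed — and
excludes void markers (Blue Dextran) by default. `estimate_mw()` inverts
the fit and flags extrapolation outside the calibrated range; this matters
here because a megadalton unknown elutes before the heaviest common
standard (thyroglobulin, 669 kDa). The copy-number range is

$$\left[\max\!\left(1, \left\lfloor \frac{m(1-\tau)}{m_1} \right\rfloor\right),\;
\left\lceil \frac{m(1+\tau)}{m_1} \right\rceil\right]$$

with relative tolerance $\tau = 0.25$ by default — the accuracy level
appropriate when a globular-standard calibration is applied to a large
non-globular assembly. A 258 kDa monomer eluting as a tetramer (1,032 kDa
apparent) yields the 3–5 copy range; across 100 seeded simulations at
0.1 mL elution noise the true copy number falls inside the reported range
in well over 95% of runs.

## Grishin distances and homolog trees

For diverged protein pairs the fraction of identical aligned positions $q$
(computed with pairwise deletion of gap columns) underestimates divergence;
the Grishin correction, which accounts for substitution-rate variation
across sites, relates identity to distance $d$ (substitutions/site) by

$$q = \frac{\ln(1 + 2d)}{2d}.$$

The map is strictly decreasing, so `grishin_distance()` inverts it by
monotone root-finding to $|\Delta q| < 10^{-9}$; $q = 1$ maps to $d = 0$,
and ~25% identity — the reported cross-species identity between distant
cage homologs — maps to $d \approx 4.67$. Pairs beyond the maximal allowed
mismatch fraction (0.85) are not dropped but capped at the distance of the
cap boundary and flagged `excluded`: tree building needs a complete matrix.
Trees are built by neighbor joining — like the Fast Minimum Evolution used
in interactive tree servers, a minimum-evolution-family distance method —
with negative branches clamped to zero and taxa sorted by name for
deterministic tie-breaking; on additive matrices of up to six taxa the
generating topology is reconstructed exactly, which is the fidelity level
that matters for a qualitative homolog-distribution tree. Distances are
computed from user-supplied alignments; database searching is out of scope.

## The synthetic-data generators

Every generator is a pure function of its arguments including the seed, and
every ground truth is verifiable by an independent brute-force check
(closed-form volumes, direct distance recomputation, column counting):

* `gen_shell()` builds a D2-symmetric pseudo-atom tetramer: chain A is the
  (y > 0, z > 0) quadrant of concentric ellipsoidal layers and chains B–D
  its two-fold images, sharing chain A's numbering. Layers are spaced two
  atom radii apart through the wall so the wall is closed to the probe —
  a two-layer wall would itself enclose a dominant spurious void — and the
  innermost layer sits one atom radius inside the inner wall face so the
  cavity boundary coincides with the ground-truth inner ellipsoid. Defaults
  (22 × 16 × 12 nm outside, 2 nm wall) mirror the real assembly; openings
  are angular masks (slits or cones) counted in the ground truth.
* `gen_pae()` plants domain blocks (4 Å within, 25 Å between, clip ceiling
  31.75 Å) with Gaussian noise; linkers draw from the between-domain mean.
* `gen_crosslinks()` rejection-samples residue pairs until exactly the
  requested numbers of satisfied and violated restraints exist, with a
  10,000-attempts-per-link infeasibility cap.
* `gen_sec()` draws elution volumes from the log-linear law (default slope
  −0.05/mL, intercept 6 — a preparative column resolving megadalton
  species) with 0.1 mL noise, appending an unlabeled unknown.
* `gen_seq_pair()` substitutes a seeded subset of positions, no gaps, so
  realized identity is within 1/length of target.

What the generators do *not* emulate: electron density, real XL/MS score
distributions and false positives, non-globular SEC migration, indels and
alignment uncertainty, and B-factor/occupancy pathologies of real
coordinate files. Passing the recovery suites therefore demonstrates the
correctness of the computations, not the error characteristics of real
data.

## Problem sizes and runtime choices

The test and acceptance workloads were sized to what the methods need, not
more: shells of 12 × 10 × 8 nm (~5,600 pseudo-atoms) for cross-link and
surface tests, the full 2,216-residue chain for domain recovery, hollow
spheres at 2 Å and 1 Å voxels for convergence, 100 seeded SEC simulations,
and additive trees to six taxa. The voxel flood fill, sphere stamping, and
component labeling are implemented in C++ (via Rcpp), as is usual for
lattice geometry in structural packages; everything else is vectorized R.

## Known limitations

* Domain boundaries from community detection depend on the resolution
  parameter; the defaults reproduce planted block structure but real PAE
  matrices with gradual inter-domain confidence may need tuning.
* Sub-probe openings narrower than ~2× the clearance margin are invisible
  to the opening detector by design.
* The ellipsoid axis estimate assumes a filled, roughly ellipsoidal cavity;
  strongly lobed cavities will report effective axes.
* Heteromeric cross-link mapping requires an explicit chain→protein
  `entities` map on the model; without one, all chains are treated as
  copies of the same protein.
* SEC copy-number inference inherits every caveat of globular calibration;
  the 25% default tolerance is a judgment call, stated in the output.
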