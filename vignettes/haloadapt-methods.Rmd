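---
title: "Methods: shell composition, structure comparison and ancestral reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shell composition, structure comparison and ancestral reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

haloadapt implements the computational core of a halophilic-adaptation
study of protein families: where in a protein's structure its amino-acid
composition is biased (buried core vs solvent-exposed surface), how a
resurrected ancestral enzyme compares with extant homologues in
three-dimensional terms, and how the ancestral sequence itself is inferred
from an alignment and a sample of phylogenetic trees. This vignette
explains the models and procedures, the tunable parameters, and the design
decisions taken where the methods literature leaves choices open.

## Accessibility and the shell partition

Solvent-accessible surface area (ASA) is computed with the Shrake–Rupley
method: each atom is inflated by the probe radius (1.4 Å, a water
molecule), test points are distributed over the inflated sphere, and a
point is occluded when it falls inside any neighbouring atom's inflated
sphere. The atom's ASA is the exposed fraction of its inflated-sphere area
$4\pi (r_{vdw}+r_{probe})^2$; a residue's ASA is the sum over its atoms.

* **Radii.** A fixed Bondi-style table (C 1.70, N 1.55, O 1.52, S 1.80,
  H 1.20, P 1.80 Å; unknown elements 1.70 Å). Published fixed radii make
  results reproducible; web servers used historically for this analysis do
  not document theirs. Hydrogens, rare in crystallographic models, are
  included when present and can be excluded with
  `sasa_params(exclude_hydrogens = TRUE)`.
* **Test points.** A deterministic golden-section spiral
  (`n_sphere_points = 960` by default). The isolated-atom case is exact by
  construction; the two-equal-spheres case, which has the closed form
  $4\pi R^2 - 2\pi R (R - d/2)$, is reproduced to well under 1% at 960
  points and is the convergence benchmark in the tests.
* **Local frames.** Each atom's point set is oriented by a frame built
  from its two nearest neighbours (ties broken by atom index on distances
  quantised at $10^{-6}$ Å$^2$). Because the frame co-rotates with the
  structure, total ASA is *exactly* invariant under rigid transforms — a
  stronger guarantee than a globally oriented point set can give. The
  trade-off: adding an atom can reorient nearby frames, so monotonicity of
  ASA under atom addition holds only up to the area of a single test
  point (about 0.13 Å$^2$ for carbon), which is how the property is
  tested.
* **Polar/charged split.** Following the spirit of surface-accounting
  servers, the residue ASA is decomposed by atom class: *charged* — the
  side-chain oxygens of Asp/Glu and side-chain nitrogens of Lys/Arg/His;
  *polar* — every other N, O and S atom (backbone amide/carbonyl, hydroxyl,
  amide and thiol groups); *nonpolar* — carbon (and hydrogen). The three
  classes sum exactly to the total.

Residues are partitioned at the conventional threshold: total ASA
≥ 5 Å² means surface exposed (**outer shell**), otherwise buried
(**inner shell**). The rule is strict (`>=`), so a residue at exactly
5 Å² is outer.

## Composition statistics

The statistical unit is the structure: each protein contributes one
20-vector of residue-type percentages per shell (summing to 100;
unknown/non-standard residues are excluded from both numerator and
denominator, and empty shells propagate as missing values rather than
zeros, to avoid biasing group means). Across groups of proteins, each
residue type is compared with a Kruskal–Wallis rank test (tie-corrected
H, chi-square p on k − 1 df; all-identical data yield the documented
convention H = 0, p = 1) followed by Dunn's post hoc pairwise z tests
with Bonferroni adjustment by default (`holm` and `none` are available —
the classical Dunn recommendation is Bonferroni and the source analyses
do not state an adjustment). Effect sizes are reported the way the
halophile literature reports them: the percent difference of a group
mean against the control group mean, signed (+70 means 70% enrichment;
−72 is printed as a 72% decrease).

## Structure comparison

Two chains are compared in four steps:

1. **Pairing.** Needleman–Wunsch global alignment of the extracted
   sequences (BLOSUM62, gap open 10, extension 0.5 — EMBOSS-needle-like
   defaults). Percent identity uses aligned columns excluding terminal
   gaps; internal gap columns count in the denominator. These choices
   matter at the percent level when reproducing published identity
   values, hence they are fixed and documented.
2. **Superposition.** The Kabsch least-squares fit over aligned, non-gap
   Cα pairs; reflections are excluded by the sign correction on the
   smallest singular value, so the rotation is always proper. RMSD is the
   residual after the fit.
3. **Domains.** Domain boundaries are configuration inputs (residue
   ranges per structure); each domain is superposed *independently*,
   matching how multi-domain enzymes are compared in practice. A domain's
   own fit can only improve on its residual under the global fit — the
   package asserts exactly this, and deliberately does not assert any
   ordering between per-domain and overall RMSD, which does not hold in
   general.
4. **Centres.** Domain centre-of-mass distance uses the unweighted Cα
   centroid by default, with atom-mass weighting behind a flag; the two
   conventions differ by well under 1 Å for compact domains, which the
   tests quantify on synthetic globules.

For the deposited ADP-dependent-kinase pair this pipeline targets, exact
domain boundaries are not annotated in the entries; the shipped defaults
(`adpk_domain_definitions()`) follow the family's lid-over-Rossmann
architecture and are explicitly approximate configuration, not data.

## Ancestral sequence reconstruction

The evolutionary model is CpREV, a reversible empirical amino-acid
replacement matrix, bundled as plain-text constants: exchangeabilities
$s_{ij}$ and stationary frequencies $\pi$. The generator is
$q_{ij} = s_{ij}\pi_j$, normalised so the expected rate
$-\sum_i \pi_i q_{ii}$ is one substitution per site per unit branch
length; detailed balance holds by construction. Transition matrices
$P(t) = e^{Qt}$ are computed through the eigendecomposition of the
$\pi^{1/2}$-symmetrised generator, which is numerically stable for
reversible models.

* **Likelihoods.** Felsenstein pruning with per-site rescaling in log
  space; gaps and ambiguity codes are missing data (partial likelihood 1
  for every state). Because the model is reversible, the likelihood and
  all marginals are invariant to root placement — a property the tests
  assert rather than assume.
* **Marginal posteriors.** For a chosen internal node, per-site posterior
  probabilities are obtained by a standard two-pass message schedule
  (equivalent to clamping the node to each state); the per-column
  posterior over 20 states sums to 1.
* **Tree samples.** The intended input is a post-burn-in posterior tree
  sample. Posteriors are averaged arithmetically over the trees in which
  the target clade (given as a leaf set) is monophyletic, and the clade's
  coverage fraction is reported. The sampling-design bookkeeping
  (`retained_samples()`) reproduces the usual arithmetic: runs ×
  generations / sampling frequency samples, a burn-in fraction discarded,
  the rest retained. Two runs of $10^7$ generations sampled every 1000
  with 40% burn-in retain 12,000 of 20,000 trees.
* **Max-posterior sequence.** Per column, the residue with the highest
  posterior; exact ties (possible under symmetric toy models) break to
  the alphabetically first one-letter code — arbitrary but deterministic.
* **Gap correction.** Whether the ancestor possessed a column at all is
  decided by unit-cost parsimony on the binary present/absent character
  (Sankoff up/down passes, exact most-parsimonious state sets).
  Parsimony-ambiguous columns resolve to *present*: the procedure's goal
  is to delete confidently absent positions, and posterior state
  information should not be discarded on a tie. With a tree sample, a
  column is kept when inferred present in at least half the trees
  containing the clade.
* **Rate heterogeneity.** Off by default (the source analyses specify
  only the replacement matrix); a discrete-gamma option (4 equal-weight
  bin-mean categories) is available behind `gamma_shape` for both
  likelihoods and posteriors.

## Synthetic data: what it emulates and what it does not

Two generators provide planted ground truth so every stage can be
validated without external data.

**Globules.** `generate_globule()` packs one bead per residue by
rejection sampling at packing fraction 0.35 (near the random-sequential-
addition limit) inside a sphere of radius $\propto n^{1/3}$, with bead
separation 3.8 Å (the Cα virtual-bond scale). Each residue is rendered as
its Cα, a pseudo side-chain atom 1.5 Å away (radially outward on the
surface, inward in the core, with an element representative of the
residue's chemistry so the polar/charged accounting is exercised), and
four carbon filler atoms 1.8 Å away standing in for the remaining heavy
atoms. The fillers give the interior a protein-like solid density: a
water-sized probe cannot percolate below the outermost bead layer, so
burial is geometrically sharp. The planted buried core is accordingly
defined as every bead deeper than 0.9 packing radii below the outermost
bead — the boundary where burial actually happens in this geometry — and
planted labels agree with the ≥ 5 Å² classifier for 94–97% of residues
at n = 500 across seeds. A fixed fraction-of-radius label boundary was
tried first and cannot be made consistent with probe burial at this size
(measured agreement plateaued near 86%), which is why the label follows
the physical burial depth. What these toys do *not* emulate: real
secondary structure, side-chain rotamers, chain connectivity, and
surface roughness; conclusions about real proteins rest on the method,
not on these shapes.

**Alignments.** `evolve_along_tree()` draws a root sequence from the
stationary frequencies (or takes one), applies per-branch substitutions
by sampling $P(t)$ rows, and superimposes indels as a Poisson process
(rate per site per unit branch length) with geometric tract lengths,
insertions creating fresh alignment columns and deletions leaving gaps;
true sequences at all internal nodes are emitted. The per-branch
sampling is exact for the model, so leaf frequencies on long branches
converge to $\pi$ and substitution counts match $P(t)$ rows — both are
goodness-of-fit tests. Not emulated: among-site rate variation in the
generator, indel-rate variation, and selection.

Study-scale choices in the tests and the acceptance script — 20 globules
of 500 residues for composition recovery, a balanced 16-leaf tree with
0.075-substitution branches and 200 sites for root-state recovery — are
small enough to run in minutes while leaving the statistical checks
well-powered (root recovery at that depth is ~90–95%, posterior
calibration bands hold at a few hundred sites).

## Numerical conventions

* Occlusion tests use a $10^{-9}$ Å² slack so exactly coincident atoms
  fully occlude each other despite floating-point rounding.
* Alternate locations in PDB input resolve to the highest occupancy, ties
  to altloc "A"; only the first model of multi-model files is read;
  HETATM records are kept in metadata, never in the protein model.
* Residue numbering is the author numbering (insertion codes preserved)
  for all reporting; chain breaks are recorded, not padded.
* Unrooted input trees are used rooted at their basal node (noted to the
  user); reversibility makes the choice immaterial for likelihoods.
* Empty shells, zero-control percent differences and clades absent from
  every tree are explicit signals (conditions/NA), never silent zeros.

## The analysis workflow

The `analysis/` directory holds the narrative drivers:
`01_simulate_inputs.R` (group manifest with planted group signatures),
`02_shell_composition.R` (accessibility → shells → composition →
Kruskal–Wallis/Dunn/percent differences, plus polar vs charged exposed
surface), `03_structure_comparison.R` (identity, overall and per-domain
RMSD, domain-centre distances on a synthetic two-domain pair, and the
deposited-coordinate comparison when those files are available), and
`04_ancestral_reconstruction.R` (tree-sample-averaged reconstruction with
gap correction, scored against the simulated truth). Each writes its
tables under `results/`. The package functions are the API; the scripts
are thin, re-runnable records of the analysis.

## Known limitations

* The polar/charged atom-class rule is a documented reconstruction of
  surface-accounting server conventions, not a reimplementation of any
  specific server; comparisons with published bar heights are
  qualitative.
* Shrake–Rupley counts cavity surface as accessible; for compact
  single-domain globules this is negligible, for porous structures it is
  not.
* Reproducing published RMSD/identity values for deposited structures
  depends on alignment scoring and domain-boundary choices; tolerances in
  the acceptance tests reflect that, and the domain defaults are
  approximate.
* The reconstruction is empirical-Bayes with fixed model parameters:
  uncertainty in the replacement model and in branch lengths beyond the
  supplied tree sample is not propagated.
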