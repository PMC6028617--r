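# haloadapt

Structural and evolutionary analysis of halophilic protein adaptation.

Proteins from organisms living at molar salt concentrations show
characteristic amino-acid biases — classically an acidic, lysine-depleted
surface and a reduced hydrophobic core. Testing whether a protein family
follows that canon (or a different strategy, such as a lysine-*enriched*
surface with an intact core) requires three quantitative pipelines, all
implemented here for structural biologists and molecular evolutionists:

1. **Shell composition.** Per-residue solvent-accessible surface area
   (Shrake–Rupley: ASA of an atom is the exposed fraction of
   4π(r_vdw + r_probe)², probe 1.4 Å), a VADAR-style decomposition into
   polar/charged/nonpolar surface, partition of residues into buried
   (ASA < 5 Å², *inner shell*) and exposed (ASA ≥ 5 Å², *outer shell*)
   sets, per-group composition tables, Kruskal–Wallis + Dunn post hoc
   comparisons, and percent differences against a control group.
2. **Structure comparison.** Needleman–Wunsch global alignment (BLOSUM62,
   gap 10/0.5) to pair Cα atoms, Kabsch least-squares superposition with
   proper-rotation enforcement, overall and per-domain RMSD
   (independent fits), and domain centre-of-mass distances (open/closed
   conformation metric).
3. **Ancestral reconstruction.** Marginal ancestral sequences under the
   CpREV empirical model: Felsenstein pruning likelihoods, per-site
   posterior distributions p(state | data) at a clade's common ancestor,
   averaging over a posterior tree sample with burn-in bookkeeping, the
   max-posterior sequence, and parsimony-based gap correction that
   deletes columns the ancestor likely never had.

A fourth module generates synthetic ground truth — compact globules with
planted core/surface compositions and alignments evolved along known
trees with indels — so every stage is validated against known answers.

## Worked example

A 300-residue globule is generated with a charged, lysine-rich planted
surface and a hydrophobic planted core, then pushed through the
accessibility and shell pipeline:

```r
library(haloadapt)

g <- generate_globule(globule_spec(
  300,
  surface_composition = aa_composition(K = 0.2, D = 0.12, E = 0.1, baseline = 0.58),
  core_composition    = aa_composition(I = 0.2, L = 0.2, A = 0.1, baseline = 0.5),
  seed = 101))
acc <- structure_asa(g$structure)        # per-residue ASA + polar/charged split
sh  <- classify_shells(acc, threshold = 5)
round(shell_composition(sh, "outer")[c("K", "D", "E", "I", "L")], 1)
#>    K    D    E    I    L
#> 17.1 14.7  8.2  3.5  5.3
round(shell_composition(sh, "inner")[c("K", "D", "E", "I", "L")], 1)
#>    K    D    E    I    L
#>  3.8  0.8  3.8 16.2 18.5
```

The outer shell recovers the planted charged surface (K 17.1% vs the
planted 20%, D+E 22.9%) while the inner shell is dominated by the planted
hydrophobics (I+L 34.7%) — the buried/exposed split found by the
classifier matches what was planted. Ancestral reconstruction is
validated the same way, against a simulated known root:

```r
m  <- cprev_model()
tr <- ape::stree(16, "balanced"); tr$edge.length <- rep(0.075, nrow(tr$edge))
tr <- ape::reorder.phylo(tr)
ev  <- evolve_along_tree(evolution_spec(tr, m, n_sites = 200, seed = 11))
rec <- reconstruct_ancestor(tr, ev$alignment, tr$tip.label, model = m)
rec
#> <ancestral_reconstruction> 200 columns, 200 present, final length 200
#>   mean max-PP 0.926; clade coverage 1.00 (1 trees)
mean(strsplit(rec$mpp_sequence, "")[[1]] == strsplit(ev$root_alignment, "")[[1]])
#> [1] 0.94
```

94% of the true root states are recovered at this depth, and the mean
maximum posterior probability (0.926) tracks that accuracy — the
posteriors are calibrated, which the test suite checks explicitly.

## The analysis workflow

`analysis/01_simulate_inputs.R` … `04_ancestral_reconstruction.R` are
thin narrative drivers over the package that rebuild the full study on
synthetic data: four structure groups with planted halophile signatures,
the shell-composition statistics (including the polar vs charged exposed
surface per group), the two-domain superposition dossier, and the
tree-sample-averaged ancestral reconstruction scored against the
simulated truth. Each writes its tables under `results/`. The methods,
parameter choices and limitations are documented in
`vignettes/haloadapt-methods.Rmd`.

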