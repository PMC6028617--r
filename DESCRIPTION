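Package: haloadapt
Title: Shell Composition, Structural Comparison and Ancestral
    Reconstruction for Halophilic Protein Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for studying halophilic adaptation of
    protein families from structures and sequences. Computes per-residue
    solvent-accessible surface area (Shrake-Rupley) with a VADAR-style
    polar/charged decomposition, partitions residues into buried (inner)
    and exposed (outer) shells at an accessibility threshold, builds
    per-group amino-acid composition tables with Kruskal-Wallis and
    Dunn's post hoc comparisons, superposes structures by the Kabsch
    algorithm with per-domain RMSD and centre-of-mass metrics, and
    performs marginal ancestral sequence reconstruction under the CpREV
    model with parsimony-based gap correction. Includes generators for
    synthetic globular structures with planted core/surface compositions
    and for alignments evolved along known trees with indels, so every
    stage can be validated against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    bio3d,
    Biostrings,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
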