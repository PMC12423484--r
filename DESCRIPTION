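Package: bfindex
Title: B-Factor Indices for Prioritizing Protein-Ligand Crystal Structures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes the Ligand B-factor Index (LBI) and Protein B-factor
    Index (PBI) from the atomic temperature factors deposited in
    macromolecular PDB files, to prioritize protein-ligand crystal
    structures for molecular docking. The binding site is defined as the
    protein heavy atoms within a chosen radius (default 10 Angstrom) of
    the bound ligand's heavy atoms; LBI is the ratio of the median
    binding-site B-factor to the median ligand B-factor, and PBI the
    ratio of the median binding-site B-factor to the median whole-protein
    B-factor. Also provides the evaluation machinery used to benchmark
    such structure-quality metrics against docking scoring functions:
    affinity-gap-constrained resampling (minBAG), Spearman ranking power,
    exponential ROC enrichment (eROCE) and enrichment factors for virtual
    screening, pose-prediction success binning, and pairwise Wilcoxon
    group comparison, together with synthetic-structure generators so the
    whole pipeline is testable offline, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
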