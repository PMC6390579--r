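Package: bindsite
Title: Deep Convolutional Prediction of Protein-Ligand Binding Residues from Sequence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-residue prediction of protein-ligand binding sites from
    amino-acid sequence features with a fully convolutional network of
    stacked LayerNorm-GLU-convolution residual blocks. Provides the
    30-dimensional residue feature embedding (normalized PSSM, solvent
    accessibility, secondary-structure propensities, dihedral angles,
    conservation scores, residue type, position), a standard decoder and a
    context-aware two-pass decoder, masked whole-sequence training with an
    L2-regularized cross-entropy objective and a three-stage learning-rate
    schedule, imbalance-aware evaluation (MCC, precision, recall, threshold
    sweeps), a synthetic corpus generator with plantable local-motif and
    long-range pair rules, and FASTA/TSV/checkpoint input-output plus a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
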