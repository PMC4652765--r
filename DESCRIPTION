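Package: gquadfret
Title: G-Quadruplex Folding Propensity from Motif Scanning, Ligand
    Fluorescence and Single-Molecule FRET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing G-quadruplex (GQ) formation in single- and
    double-stranded DNA. Scans sequences for G3N1-7 quadruplex motifs and
    predicts the folded conformation (parallel, antiparallel, unfolded) and
    folding propensity from the loop-length profile and strandedness
    context. Processes N-methyl mesoporphyrin IX (NMM) and Crystal Violet
    (CV) emission spectra into normalized two-channel readouts and assigns
    conformation classes by nearest-centroid classification; classifies
    circular dichroism spectra by their 240/260/290 nm signatures.
    Simulates two-channel single-molecule FRET trace datasets (two FRET
    states, donor-only molecules, photobleaching, reversible
    folding/unfolding dynamics) and quantifies folded fractions by
    two-Gaussian fitting of FRET histograms, including dual-label
    selection, photobleach truncation and dynamic-trace detection.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    data.table,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
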