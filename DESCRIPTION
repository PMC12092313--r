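Package: evonas
Title: Evolutionary Cell-Based Neural Architecture Search for Cardiac PET
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aged (regularized) evolutionary search over cell-based
    convolutional architecture genomes for three-class classification of
    cardiac amyloidosis sub-types (AL, ATTR) versus controls from 2D PET
    slices. Provides DAG cell genomes with mutation operators, a
    genome-to-network compiler with a self-contained CNN training engine
    (Rcpp kernels), a two-phase lower-fidelity performance estimation
    protocol, a patient-level data pipeline with affine augmentation, and
    a seeded synthetic PET-phantom generator emulating the study cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp,
    RNifti,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
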