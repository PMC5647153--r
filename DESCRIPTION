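Package: hnsmodes
Title: Cooperative DNA-Binding, Conformational, and Bridging Analyses for
    H-NS Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis toolkit for studies of the bacterial
    nucleoid-associated protein H-NS and its DNA binding modes. Implements
    the McGhee-von Hippel cooperative lattice-binding isotherm together with
    an exact finite-lattice transfer-matrix reference, weighted orthogonal
    distance regression for estimating the association constant and
    cooperativity from tethered particle motion (TPM) titrations, conversion
    of TPM root-mean-square bead excursions to apparent persistence lengths
    and fractional coverage, residue-residue contact-probability maps and
    per-residue ion contact profiles from molecular dynamics trajectory
    ensembles, detection and classification of alpha-helix hydrogen-bond
    buckles, and quantification of DNA-bridging recovery from scintillation
    counts including four-parameter logistic titration transitions. Seeded
    synthetic-data generators produce every input the analyses consume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
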