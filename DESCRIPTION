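Package: ionpore
Title: Ion-Site Assignment, Pore Profiling and Bi-Ionic Selectivity for Channel Cryo-EM Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for three analyses used to characterize cation channels
    resolved by cryo-EM, built around the lysosomal K+ channel TMEM175 as the
    motivating system: (1) assignment of ion-binding sites by comparing
    non-protein density peaks between maps determined in K+ and Cs+, exploiting
    the roughly three-fold stronger electron scattering of Cs+; (2) probe-radius
    profiling of the ion-conduction pathway with hydrophobicity annotation and
    constriction (gate) detection; (3) bi-ionic reversal-potential and
    permeability-ratio analysis of whole-cell current-voltage recordings. A
    synthetic-data module generates toy channels, paired density maps and
    voltage-clamp families with known ground truth so the full pipeline is
    testable without downloading depositions. All user-facing functions take
    and return tidy tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
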