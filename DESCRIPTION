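Package: dscfit
Title: Two-State Analysis of Protein Thermal Denaturation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for equilibrium two-state analysis of protein thermal
    denaturation. Fits excess heat-capacity thermograms from differential
    scanning calorimetry (DSC) to the two-state van't Hoff model, yielding
    the transition temperature, the calorimetric enthalpy and the van't
    Hoff enthalpy together with the diagnostic ratio of the two
    enthalpies; processes raw scans (buffer subtraction, molar
    normalization, progress-baseline removal); fits sigmoidal circular
    dichroism melts with sloping baselines; analyses ligand-induced
    melting-temperature shifts with a single-site binding linkage model;
    and predicts unfolding heat-capacity and enthalpy changes from
    apolar/polar accessible-surface-area changes via empirical
    structure-energetics correlations, including a Shrake-Rupley
    accessible-surface-area engine and a PDB reader. A seeded synthetic
    data generator produces thermograms, melts, titration series and toy
    structures for validation.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    bio3d,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
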