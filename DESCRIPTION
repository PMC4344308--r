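Package: scasector
Title: Statistical Coupling Analysis Sectors Versus Sequence Conservation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for statistical coupling analysis (SCA) of protein multiple
    sequence alignments using the projection method, relative-entropy (Kullback-
    Leibler) sequence conservation, and a statistical battery comparing the
    functional predictive power of SCA sectors against equally sized sets of
    conserved residues (Fisher exact enrichment, chi-squared table comparison,
    Mann-Whitney effect-distribution tests, sector-size sweeps). Includes a
    structural "touching" analysis of insertion sites via fixed-radius spheres
    on peptide-bond atoms, an analytic model of the SCA matrix's top eigenmode
    with simulation experiments on the scaling of off-diagonal correlations
    with alignment depth, and seeded synthetic alignment and mutational-effect
    generators for fully reproducible in silico studies.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
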