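Package: acrydock
Title: Covalent Docking and Cysteine Reactivity Profiling for Acrylamide Adducts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to predict which protein cysteines react with acrylamide
    via Michael addition and to characterise the resulting propionamide
    adduct's binding site. Provides structure input/output with minimal
    force-field parameter assignment, per-cysteine profiling (solvent
    accessible surface area, relative acidity, deprotonation penalty and
    5 Angstrom microenvironment), restraint-based covalent pose generation
    with Monte-Carlo refinement and a weighted composite score, pose
    clustering by interface RMSD, cluster-size-weighted interaction
    fingerprints split by the adduct carbonyl and amino groups, and
    within-protein ranking of candidate modification sites. A synthetic
    pocket generator produces fully self-contained test systems with planted
    microenvironments and interaction geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
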