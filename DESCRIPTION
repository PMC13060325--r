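Package: pepmcts
Title: Surrogate-Guided Monte Carlo Tree Search Design of Plastic-Binding Peptides
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discovery engine for short plastic-binding peptides. A recurrent
    sequence-to-score surrogate is trained on biophysical peptide:score tables
    and drives a constrained UCB1 Monte Carlo tree search over amino-acid
    sequence space, with multi-objective rewards that trade binding affinity
    against water solubility or against a competing plastic surface. Includes
    sampling-based Shapley attribution of predictions to residue positions,
    amino-acid composition and enrichment analytics, and a calibrated
    synthetic scoring oracle so that every stage of the pipeline can be
    exercised and tested without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
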