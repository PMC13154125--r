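Package: xtalgroup
Title: Space-Group Preference Prediction for Organic Molecules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the likely crystallographic space group(s) of an organic
    molecule from its molecular structure. Implements the full analysis
    pipeline: a synthetic molecule/space-group generator built on a
    valence-correct fragment grammar (standing in for licence-restricted
    crystal-structure databases), dataset curation for polymorph handling and
    balanced subsets, point-group symmetry detection, geometric/general/
    chemical molecular descriptors, attributed molecular graphs, a random
    forest track and graph neural network tracks (edge-conditioned message
    passing and an E(3)-invariant variant), and a top-N evaluation framework
    with frequency and random reference baselines, scaled precision/recall,
    cross-validation, and permutation feature importance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    randomForest,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
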