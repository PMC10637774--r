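Package: fragforge
Title: Reinforcement-Learning Design of Aromatic Fragments with
    Biolayer-Interferometry Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for fragment-based inhibitor discovery:
    a character-level GRU language model over SMILES strings is pretrained
    by maximum likelihood and fine-tuned with augmented-likelihood
    reinforcement learning against a composite reward (a modest-similarity
    band to a positive set of known inhibitors, descriptor-space RMSD
    proximity, aromaticity and structure-alert gates). Campaign output is
    triaged by validity, deduplication, top-K ranking and Tanimoto search
    of a commercial fragment library, and candidate fragments are installed
    onto a parent scaffold. A biolayer-interferometry module simulates 1:1
    Langmuir sensorgrams, applies four-sensor double referencing
    (a-c)-(b-d), and fits global binding kinetics (kon, koff, Kd).
    Synthetic-data generators provide every input, so the whole pipeline
    runs hermetically.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve
SystemRequirements: OpenBabel command-line tool (obabel) on PATH
Config/testthat/edition: 3
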