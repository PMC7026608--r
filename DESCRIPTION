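Package: noetools
Title: Reconciling RNA Conformational Ensembles with Sparse NOE Distance Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Post-simulation analysis of RNA conformational ensembles against
    sparse NMR data. Implements the r^-6 NOE forward model with
    inequality-restrained ensemble averages, a-posteriori maximum-entropy
    reweighting with a Gaussian error prior and Kish effective-sample-size
    diagnostics, two-stage conformational clustering (glycosidic syn/anti
    bitstring pre-clusters followed by weighted maximum-clique clustering
    under an eRMSD cutoff), maximum-parsimony search for minimal cluster sets
    that satisfy every NOE threshold ranked by Kullback-Leibler divergence,
    and a sequence-independent eRMSD motif search against a structure library
    accelerated by the metric's triangle inequality. Includes a synthetic
    fixture generator producing multi-state toy ensembles with known ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    boot,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    igraph,
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
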