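Package: pheflux
Title: Transcriptome-Conditioned Metabolic Flux Inference by Maximum Entropy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers a unique genome-scale metabolic flux distribution
    conditioned on a transcriptome by maximizing the Shannon entropy of
    fluxes per mRNA over the steady-state flux polytope, which is
    equivalent to minimizing the forward Kullback-Leibler divergence
    between the flux and expression distributions.  Provides readers for
    SBML-FBC and JSON genome-scale metabolic models, gene-protein-reaction
    rule evaluation, the SPOT and FBA plus l2-minimization baselines, a
    uniform flux-polytope sampler with a lambda-controlled synthetic
    transcriptome generator for benchmarking, and downstream phenotype
    statistics (glucose-to-lactate yield, pathway enrichment indices,
    Mann-Whitney group comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    Matrix,
    methods,
    pracma,
    purrr,
    quadprog,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
Suggests:
    nloptr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
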