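Package: pharmnet
Title: Network Pharmacology with Multiscale Diffusion Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for network-pharmacology analysis of multi-compound
    interventions such as herbal medicines. Builds and filters
    compound-target networks, quantifies target overlap with a disease
    protein set (exact hypergeometric tests and a randomized
    fold-enrichment null), performs pathway over-representation analysis
    against GMT gene-set libraries, computes diffusion profiles of
    compounds and diseases on a multiscale protein/biological-function
    network by random walk with restart, ranks compounds by
    diffusion-profile correlation, and extracts top-k mechanism
    subnetworks. Includes a seeded synthetic-data generator that emulates
    the statistical structure of real interactomes so the whole pipeline
    is testable without database access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'synthetic-data.R'
    'network-assembly.R'
    'enrichment.R'
    'diffusion.R'
    'mechanism.R'
    'pipeline.R'
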