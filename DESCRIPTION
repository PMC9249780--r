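Package: fluxtarget
Title: Transcriptomics-Informed Metabolic Modeling for Drug Target Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate metabolic drug-repurposing targets by combining
    constraint-based modeling of genome-scale metabolic networks with network
    topology. Expression data are binarized and clustered into medoids, a
    flux-consistent context-specific model is extracted per medoid, flux balance
    analysis is run over a simplex-lattice design of weighted objectives
    (biomass, ATP, and a membrane-lipid product), and each non-redundant optimum
    is analyzed for choke points - including the stringent "extended choke
    point" class - and reaction-centric PageRank centrality. Reactions that are
    essential, linked to tumor-upregulated genes, and recurrently extended choke
    points and/or topologically central are aggregated into gene and
    chemical-gene relevance rankings. Includes readers for COBRA-style JSON and
    a minimal SBML Level 3 FBC subset, a synthetic fixture generator with
    planted ground truth, and a stage-per-subcommand command line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    cluster,
    igraph,
    jsonlite,
    xml2,
    yaml,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
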