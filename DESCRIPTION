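Package: mycohub
Title: Mycobiome Diversity, Producer-ASV Screening, Nestedness and
    Co-Occurrence Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of amplicon-derived fungal community (ASV)
    tables from plant tissues: alpha and beta diversity with rarefaction,
    NMDS ordination and PERMANOVA; dual-evidence identification of potential
    metabolite-producing ASVs by semi-global sequence identity against
    reference producer strains and Kendall tau-b correlation of tissue-mean
    abundance with metabolite concentration; NODF nestedness and a packed
    matrix temperature with occurrence-preserving null models; a simplified
    negative-binomial Wald test for differential abundance; and signed
    co-occurrence networks with fast-greedy modules, Zi-Pi keystone roles,
    random-graph baselines, power-law degree fits and facilitator-genus
    ranking. Includes a seeded synthetic-data generator with planted ground
    truth (nested tissue occupancy, producer ASVs tracking a metabolite
    gradient, latent co-abundance modules) so the full pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    igraph,
    vegan,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
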