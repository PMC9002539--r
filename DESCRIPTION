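Package: OralGuilds
Title: Paired-Design Guild Analysis of the Oral Microbiome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for paired-design (pre/post intervention)
    oral microbiome studies with a phenotype contrast between PROP taster
    groups: phylogenetic alpha diversity (observed ASVs, Shannon, Pielou
    evenness, Faith's PD), weighted and unweighted UniFrac, PCoA and
    covariate-adjusted PCoA, PERMANOVA with subject-stratified (restricted)
    permutation schemes, repeated-measures (Bland-Altman) correlation,
    dichotomic tree-based co-abundance guild construction, guild-phenotype
    association via linear mixed models with BH false-discovery control, and
    tripartite guild/protein/sensory correlation networks. A synthetic-data
    generator with planted guild structure and planted group and intervention
    effects makes every stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ape,
    nlme,
    igraph,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    picante,
    mclust,
    phangorn,
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'rmcorr.R'
    'associations.R'
    'cohort.R'
    'diversity.R'
    'guilds.R'
    'io.R'
    'ordination.R'
    'synthetic.R'
    'pipeline.R'
    'prop.R'
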