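Package: guildflow
Title: Guild-Based Analysis of Microbiome Resilience in Fermentation Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers co-abundance groups (CAGs, "guilds") from 16S ASV count
    tables in repeated-measures fermentation designs and tests their response
    to treatments and short-chain fatty acid chemistry. Implements
    repeated-measures (Bland-Altman) correlation, Ward clustering of the
    1-correlation distance with sequential top-down PERMANOVA delimitation of
    guilds, co-abundance networks, Bray-Curtis ordination with
    covariate-adjusted PCoA, subject-stratified pairwise PERMANOVA,
    Procrustes/PROTEST concordance, and per-guild linear mixed models versus
    treatments and metabolites with Benjamini-Hochberg FDR control. Ships a
    synthetic-community generator with planted guild structure, donor random
    effects, and SCFA/pH chemistry coupled to fermenter-guild abundance, so
    every stage of the pipeline is verifiable against known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vegan,
    ape,
    igraph,
    lme4,
    lmerTest,
    emmeans,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    biomformat,
    mclust
Config/testthat/edition: 3
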