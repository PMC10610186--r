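Package: mzosim
Title: Simulating Latitudinal and Elevational Gradients of Phylogenetic
    Diversity under Single and Multiple Zones of Origin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test the tropical niche conservatism (TNC) and
    multiple zones of origin (MZO) hypotheses for the assembly of tree
    communities along latitudinal and elevational gradients.  Provides a
    birth-death phylogeny simulator with extinct-lineage pruning, a
    continuous-time Markov model of biogeographic region shifts among
    tropical/temperate lowland/highland zones, regional-pool community
    sampling, the standardized effect size of mean pairwise phylogenetic
    distance (MPD_ses) with a richness-controlled null, gradient
    regressions of diversity on latitude and elevation with
    replicate-level aggregation and Kolmogorov-Smirnov scenario
    comparison, an empirical pipeline for forest-plot inventories
    (stem filtering, community matrices, plot-size residualization,
    gradient models, and a height-vessel-diameter analysis with a
    biogeographic-origin covariate), and a synthetic-data generator that
    emulates an Andean plot network for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    Matrix,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
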