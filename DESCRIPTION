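Package: cedamimic
Title: Categorical Exploratory Data Analysis with Structure-Preserving Mimicking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Categorical exploratory data analysis (CEDA) for mixed-type
    data matrices. Every feature -- continuous, discrete or categorical --
    is given a categorical nature via a possibly-gapped histogram; pairwise
    association is measured by re-scaled directional conditional Shannon
    entropies and their mutual conditional entropy (MCE) matrix; higher-order
    dependency is displayed through contingency-kD-lattices permuted by
    hierarchical-clustering trees into block-structured heatmaps. Observed
    categorical patterns (zero cells, column modes, orderings, unimodality,
    composite-category mass) are certified by a bootstrap reliability check
    and turned into hard rules. Three mimicking protocols then generate
    ensembles of surrogate data matrices that preserve the certified
    deterministic and stochastic structure: constrained categorical table
    simulation, block-wise PCA with kernel-smoothed component resampling for
    continuous features, and a mixed protocol combining both.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    igraph,
    ape
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'data-model.R'
    'categorize.R'
    'entropy.R'
    'lattice.R'
    'rules.R'
    'mimic-block.R'
    'mimic-scenarios.R'
    'fixtures.R'
    'pipeline.R'
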