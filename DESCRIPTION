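Package: metaparc
Title: Meta-Analytic Co-Activation Parcellation and Functional Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coordinate-based meta-analysis toolkit for connectivity-based
    parcellation of brain regions and their functional characterization.
    Builds voxel-wise meta-analytic co-activation (MACM/ALE) profiles from
    activation-foci databases using nearest-experiment spatial filters,
    parcellates seed regions by k-means clustering with filter-range and
    cluster-number selection driven by stability criteria (deviants,
    variation of information, silhouette, cluster-separation ratio,
    hierarchy index), quantifies atlas overlap via the Jaccard index,
    performs Bayesian reverse-inference decoding of regions against
    term-annotated coordinate databases (posterior probabilities,
    chi-square tests, Benjamini-Hochberg FDR, Bayes factors), and performs
    systems-level decoding of seed-cortex region pairs with a quasi-null
    cortical decoding, term intersection and region-ID set difference.
    Includes a synthetic foci-database generator with planted cluster
    structure and planted term-system associations for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    cluster,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
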