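Package: cuvarp
Title: Cumulative Variation Partitioning with Multiple Response and Predictor Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-matrix variation partitioning for community ecology. Implements
    cumulative variation partitioning (CUVARP), in which several community and
    predictor matrices (native community, alien community, environment, space) are
    each summarised by principal coordinates of Gower dissimilarities or by
    distance-based Moran eigenvector maps, reciprocally partitioned by partial
    redundancy analysis on the adjusted R-squared scale, and assembled into a single
    variance-unit diagram whose non-overlap regions are residual variation. Includes
    Gower and Euclidean dissimilarities for mixed variable types, principal
    coordinates analysis, redundancy analysis with Ezekiel-adjusted R-squared,
    restricted (block, series, split-plot) Monte Carlo permutation tests with
    Freedman-Lane residualisation, forward selection with a double stopping rule and
    false discovery rate control, Rao quadratic entropy, community-weighted means,
    and a synthetic riverscape generator with known variance structure for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite, yaml, vegan
Suggests: testthat (>= 3.0.0), withr, cluster, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'cuvarp-package.R'
    'utils.R'
    'ordination.R'
    'dissimilarity.R'
    'diversity_traits.R'
    'spatial_mem.R'
    'inference.R'
    'varpart.R'
    'cuvarp_pipeline.R'
    'synthdata.R'
    'tables_io.R'
    'reporting.R'
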