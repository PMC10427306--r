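Package: campkin
Title: Kinship Structure of Hunter-Gatherer Residential Camps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the kinship structure of small-scale,
    mobile forager populations organised into residential camps. Computes
    pedigree-based kinship and Wright's coefficient of relatedness from
    genealogy tables, the shared reproductive interest statistic that
    extends relatedness to affinal ties, three levels of within-group
    relatedness aggregation, kin-network dispersion across camps, camp
    composition stability, spouse consanguinity and age-gap summaries,
    permutation tests for group differences, partial correlations, and
    relatedness-versus-distance analyses. Includes a gene-dropping
    Monte Carlo identity-by-descent estimator as an independent check on
    the kinship recursion, and a synthetic genealogy generator with
    configurable post-marital dispersal rules (bilocal, patrilocal,
    matrilocal) for calibration and simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
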