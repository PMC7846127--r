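Package: kinfst
Title: Kinship and F_ST Estimation for Arbitrary Population Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Method-of-moments estimation of kinship matrices, inbreeding
    coefficients and the generalized F_ST under arbitrary population
    structures. Implements a consistent kinship estimator based on a
    pairwise genotype statistic rescaled by its minimum between
    subpopulations, alongside the classical estimators it is compared
    against (the standard genetic-relatedness-matrix estimator,
    Weir-Cockerham, Weir-Hill, Hudson pairwise and its K-population
    generalization, and the Weir-Goudet individual-level estimator),
    their closed-form asymptotic limits, and a Balding-Nichols /
    admixture (BN-PSD) simulator with a one-dimensional geography used
    to validate them. Genotypes are read from plink BED/BIM/FAM or TSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
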