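Package: recessmap
Title: Recessive-Model Association Testing and Power Analysis for Admixed Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide association analysis under a recessive
    genetic model in admixed, family-structured cohorts, motivated by
    recessive type 2 diabetes discovery in the Greenlandic population.
    Provides a synthetic admixed-cohort generator (Balding-Nichols ancestral
    frequencies, Dirichlet admixture proportions, binomial genotypes and a
    recessive-effect disease model), OGTT-based phenotype derivation
    (glucose-tolerance classification, HOMA-IR, Gutt's ISI(0,120),
    within-stratum rank-based inverse normal transformation), additive versus
    recessive case-control power simulation over an (EAF, OR) grid,
    covariate-adjusted logistic association, an EMMA-style linear mixed model
    with a genetic relatedness matrix for relatedness-aware discovery p
    values, genomic-inflation diagnostics, and a two-step bootstrap
    maximum-likelihood estimator of ancestry-specific allele frequencies
    under the binomial admixture likelihood.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    vcfR,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
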