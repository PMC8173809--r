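Package: podabc
Title: Coalescent Simulation and Random-Forest ABC for Podolian Cattle Demography
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Demographic inference toolkit for the origins of Podolian (grey
    steppe) cattle. Provides a backward-in-time coalescent simulator for
    user-defined demographic scenarios (population splits, size changes,
    bottlenecks and admixture pulses) with SNP-chip-like ascertainment, six
    built-in colonization scenarios contrasting Mediterranean, Balkan and
    admixture routes under one- or two-wave models, and approximate Bayesian
    computation with random forests (ABC-RF) for scenario choice (votes and
    posterior probability) and quantile-forest parameter estimation.
    Supporting tools cover PLINK-dialect text genotype input/output, minor
    allele frequency and call-rate filtering, linkage-disequilibrium pruning
    (pairwise r2 and variance-inflation-factor rules), heterozygosity and
    allele-frequency summaries, LD-based effective population size
    trajectories, identity-by-state, Reynolds, Nei and Hudson FST distances,
    f3 admixture statistics, classical multidimensional scaling, genotype
    principal component analysis and a Mahalanobis-distance selection-outlier
    scan with Storey q-values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    Rcpp,
    ranger,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
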