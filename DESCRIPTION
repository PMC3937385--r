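Package: msatdem
Title: Microsatellite Population Genetics and Coalescent-Based Demographic
    Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for diploid microsatellite data with sex-linked (Z) loci:
    GenePop input/output with population, sex and linkage metadata; per
    population diversity statistics (heterozygosity, allelic richness by
    rarefaction, F_IS, permutation tests of Hardy-Weinberg equilibrium);
    pairwise differentiation (Weir-Cockerham theta with genotype permutation
    tests, Jost's D_est with bootstrap intervals); a backward-time coalescent
    simulator for multi-population split/admixture scenarios under stepwise
    mutation models; approximate Bayesian computation for demographic scenario
    choice (direct and logistic-regression estimates) and regression-adjusted
    parameter posteriors with highest-posterior-density intervals; and
    post-processing of external Bayesian clustering runs (Evanno's delta-K,
    cluster label alignment).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    glmnet,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
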