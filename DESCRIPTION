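Package: epsstrat
Title: Population Stratification Confounding Under Extreme Phenotype Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation toolkit quantifying the inflation of the type 1
    error rate caused by population stratification when genetic association
    studies genotype only the phenotypic extremes of a cohort (extreme
    phenotype sampling). Provides closed-form results for the
    two-subpopulation normal-mixture model (mixture genotype frequencies,
    conditional phenotype distributions, and an analytic large-sample false
    positive rate for the extreme-sampling design), cohort and sampling-design
    simulators, the standard single-SNP association tests (Pearson chi-square,
    Cochran-Armitage trend, two-proportion, ANOVA, linear and logistic
    regression), Balding-Nichols and frequency-panel ancestry-SNP simulators
    with EIGENSTRAT-style genotype standardization and principal-component
    scores, and Monte-Carlo experiment runners that estimate false positive
    rates per sampling design, genetic model and ancestry-adjustment strategy.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
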