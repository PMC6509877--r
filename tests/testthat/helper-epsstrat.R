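# Shared helpers for the Monte-Carlo reproduction checks.

# Binomial 3-standard-error tolerance for comparing a reproduced rejection
# proportion (R replicates) against a published Monte-Carlo estimate
# (paper_R replicates): |r_hat - printed| <= 3 sqrt(rbar (1 - rbar) / R_eff)
# with R_eff = min(R, paper_R) and rbar the pooled estimate.
mc_tolerance <- function(r_hat, printed, R, paper_R = 10000) {
  r_eff <- min(R, paper_R)
  rbar <- (R * r_hat + paper_R * printed) / (R + paper_R)
  3 * sqrt(rbar * (1 - rbar) / r_eff)
}

expect_rate <- function(r_hat, printed, R, paper_R = 10000) {
  tol <- mc_tolerance(r_hat, printed, R, paper_R)
  expect_lte(abs(r_hat - printed), tol)
}

# Extract one cell's fpr from a runner result data frame.
cell_fpr <- function(res, design, model) {
  res$fpr[res$design == design & res$genetic_model == model]
}

# Tiny deterministic design sample for the association-test unit tests.
toy_sample <- function(genotype, group, phenotype = NULL) {
  structure(list(design = "eps", genotype = as.integer(genotype),
                 phenotype = phenotype %||% rep(0, length(genotype)),
                 group = group, indices = seq_along(genotype)),
            class = "design_sample")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
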