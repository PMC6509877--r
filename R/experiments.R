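# Monte-Carlo experiment runners: estimate the false positive rate per
# sampling design, genetic model and (for the ancestry arm) adjustment
# strategy. Each replicate draws its own seed from the root seed via
# replicate_seed(), so runs are reproducible and extendable: the first R
# replicates of a longer run are identical to a run of length R.
#
# Bookkeeping convention: a replicate whose test is degenerate
# (valid = FALSE) counts as a non-rejection and is tallied in n_invalid.

DESIGNS <- c("eps", "random", "case_control")
MODELS <- c("codominant", "additive", "recessive")

fpr_row <- function(scenario_id, design, genetic_model, test, n_reps,
                    n_rejections, n_invalid) {
  fpr <- n_rejections / n_reps
  data.frame(scenario = scenario_id, design = design,
             genetic_model = genetic_model, test = test,
             n_reps = n_reps, n_rejections = n_rejections,
             n_invalid = n_invalid, fpr = fpr,
             mc_se = sqrt(fpr * (1 - fpr) / n_reps),
             stringsAsFactors = FALSE)
}

# Apply the design-appropriate test for one genetic model to one sample.
# Binary designs use the contingency-table tests; the random design uses
# quantitative tests on the retained phenotype.
run_design_test <- function(sample, genetic_model) {
  if (sample$design == "random") {
    switch(genetic_model,
      codominant = anova_test(sample$phenotype,
                              factor(sample$genotype, levels = 0:2)),
      additive = linear_trend_test(sample$phenotype, sample$genotype),
      recessive = anova_test(sample$phenotype, sample$genotype == 2L))
  } else {
    tab <- build_table(sample, genetic_model)
    switch(genetic_model,
      codominant = pearson_chisq(tab),
      additive = cochran_armitage(tab),
      recessive = two_proportion_test(tab))
  }
}

#' Estimate false positive rates for one scenario
#'
#' For each replicate: simulate a cohort, draw each requested design's
#' subsample from that same cohort (shared cohorts reduce the variance of
#' between-design contrasts), apply the design-appropriate test per
#' genetic model, and record whether the null is rejected at
#' `params$alpha`. Degenerate tests count as non-rejections and are
#' tallied.
#'
#' @param params A [scenario_params()] object.
#' @param designs Subset of `c("eps", "random", "case_control")`.
#' @param models Subset of `c("codominant", "additive", "recessive")`.
#' @param n_reps Number of Monte-Carlo replicates.
#' @param seed Root seed (per-replicate seeds derived via
#'   [replicate_seed()]).
#' @param scenario_id Label recorded in the output.
#' @return A data frame with one row per design x model: replicate count,
#'   rejection count, invalid count, `fpr`, and Monte-Carlo standard
#'   error `mc_se`.
#' @examples
#' sp <- scenario_params(omega1 = 0.3, mu1 = 0.1, p1 = 0.5, p2 = 0.7,
#'                       N = 1000)
#' run_scenario(sp, designs = "eps", models = "additive",
#'              n_reps = 50, seed = 1)
#' @export
run_scenario <- function(params, designs = DESIGNS, models = MODELS,
                         n_reps = 10000L, seed = 1L,
                         scenario_id = "scenario") {
  stopifnot(inherits(params, "scenario_params"), n_reps >= 1)
  designs <- match.arg(designs, DESIGNS, several.ok = TRUE)
  models <- match.arg(models, MODELS, several.ok = TRUE)
  n <- params$n
  rej <- inv <- matrix(0L, nrow = length(designs), ncol = length(models),
                       dimnames = list(designs, models))
  for (i in seq_len(n_reps)) {
    set.seed(replicate_seed(seed, i))
    cohort <- simulate_cohort(params)
    for (d in designs) {
      smp <- switch(d,
        eps = eps_sample(cohort, n),
        random = random_sample(cohort, 2L * n),
        case_control = case_control_sample(cohort, n))
      for (mod in models) {
        res <- run_design_test(smp, mod)
        if (!res$valid) {
          inv[d, mod] <- inv[d, mod] + 1L
        } else if (res$p_value < params$alpha) {
          rej[d, mod] <- rej[d, mod] + 1L
        }
      }
    }
  }
  do.call(rbind, lapply(designs, function(d)
    do.call(rbind, lapply(models, function(mod) {
      test <- if (d == "random")
        switch(mod, codominant = "anova", additive = "linear_regression",
               recessive = "anova")
      else switch(mod, codominant = "pearson_chisq",
                  additive = "cochran_armitage",
                  recessive = "two_proportion")
      fpr_row(scenario_id, d, mod, test, n_reps, rej[d, mod], inv[d, mod])
    }))))
}

#' Run the full two-population parameter grid
#'
#' Crosses the study's parameter grid — mixing proportion `omega1` in
#' \{0.3, ..., 0.7\}, "A"-allele frequencies `p1`, `p2` each in
#' \{0.5, ..., 0.9\}, phenotype mean `mu1` in \{0.1, 0.2\} — over the
#' requested designs and genetic models (250 scenarios by default).
#'
#' @param n_reps Replicates per scenario.
#' @param seed Root seed; each scenario uses an offset root so scenarios
#'   are independent.
#' @param omega1_grid,p_grid,mu1_grid Grid values (defaults as above).
#' @param designs,models As in [run_scenario()].
#' @param N,tail_fraction,alpha Scenario constants.
#' @return Row-bound [run_scenario()] results with columns `omega1`,
#'   `mu1`, `p1`, `p2` prepended.
#' @export
run_table1_grid <- function(n_reps = 10000L, seed = 1L,
                            omega1_grid = seq(0.3, 0.7, by = 0.1),
                            p_grid = seq(0.5, 0.9, by = 0.1),
                            mu1_grid = c(0.1, 0.2),
                            designs = DESIGNS, models = MODELS,
                            N = 5000L, tail_fraction = 0.1, alpha = 0.05) {
  grid <- expand.grid(omega1 = omega1_grid, p1 = p_grid, p2 = p_grid,
                      mu1 = mu1_grid, KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    params <- scenario_params(omega1 = g$omega1, mu1 = g$mu1,
                              p1 = g$p1, p2 = g$p2, N = N,
                              tail_fraction = tail_fraction, alpha = alpha)
    res <- run_scenario(params, designs, models, n_reps,
                        seed = replicate_seed(seed, i),
                        scenario_id = sprintf("grid_%03d", i))
    out[[i]] <- cbind(g[rep(1, nrow(res)), c("omega1", "mu1", "p1", "p2")],
                      res, row.names = NULL)
  }
  do.call(rbind, out)
}

#' Sample-size scaling experiment (mild stratification)
#'
#' Fixes a mild-stratification scenario (`omega1 = 0.1`, `mu1 = 0.1`,
#' `p1 = 0.7`, `p2 = 0.6`) and scales the cohort from which the 10%
#' extremes are drawn across `cohort_sizes`, so the total subsample is
#' 0.2 x cohort size (2,000 / 4,000 / 10,000 by default).
#'
#' @param n_reps Replicates per cohort size.
#' @param seed Root seed.
#' @param cohort_sizes Cohort sizes (default 10,000; 20,000; 50,000).
#' @param designs,models As in [run_scenario()].
#' @return Row-bound results with columns `N` and `subsample` prepended.
#' @export
run_sample_size_scaling <- function(n_reps = 10000L, seed = 1L,
                                    cohort_sizes = c(10000L, 20000L, 50000L),
                                    designs = c("eps", "random"),
                                    models = MODELS) {
  out <- vector("list", length(cohort_sizes))
  for (i in seq_along(cohort_sizes)) {
    N <- cohort_sizes[i]
    params <- scenario_params(omega1 = 0.1, mu1 = 0.1, p1 = 0.7, p2 = 0.6,
                              N = N, tail_fraction = 0.1)
    res <- run_scenario(params, designs, models, n_reps,
                        seed = replicate_seed(seed, i),
                        scenario_id = sprintf("scaling_N%d", N))
    out[[i]] <- cbind(data.frame(N = N, subsample = 2L * params$n),
                      res, row.names = NULL)
  }
  do.call(rbind, out)
}

# One replicate of the ancestry-correction experiment. Returns a named
# logical/NA vector of rejections for the requested model x adjustment
# cells (NA = invalid).
pc_correction_replicate <- function(mode, params, mu_vector, bn, panel,
                                    models, adjust, n_pcs,
                                    candidate_threshold) {
  if (mode == "balding_nichols") {
    cohort <- simulate_cohort(params)
    smp <- eps_sample(cohort, params$n)
    pop <- cohort$population[smp$indices]
    candidate <- smp$genotype
  } else {
    cohort <- simulate_multipop_cohort(
      N = 5000L, phenotype_means = mu_vector, sigma2 = 1)
    smp <- eps_sample(cohort, round(0.1 * length(cohort$phenotype)))
    pop <- cohort$population[smp$indices]
  }
  need_pcs <- "adjusted" %in% adjust
  if (mode == "balding_nichols") {
    if (need_pcs) {
      freqs <- balding_nichols_freqs(bn, n_pops = 2L)
      G <- simulate_panel_genotypes(freqs, pop)
    }
  } else {
    G <- simulate_panel_genotypes(panel, pop)
    j <- tryCatch(select_confounded_candidate(G, pop,
                                              threshold = candidate_threshold),
                  epsstrat_no_candidate = function(e) NA_integer_)
    if (is.na(j)) {
      out <- rep(NA, length(models) * length(adjust))
      names(out) <- as.vector(outer(models, adjust, paste, sep = "."))
      return(out)
    }
    candidate <- G[, j]
  }
  pcs <- if (need_pcs)
    compute_pcs(standardize_genotypes(G)$standardized, k = n_pcs) else NULL
  out <- c()
  for (adj in adjust) {
    cov <- if (adj == "adjusted") pcs else NULL
    for (mod in models) {
      res <- logistic_lrt(smp$group, candidate, covariates = cov,
                          genetic_model = mod)
      out[paste(mod, adj, sep = ".")] <-
        if (!res$valid) NA else res$p_value < 0.05
    }
  }
  out
}

#' Ancestry (principal-component) correction experiment
#'
#' Per replicate: simulate a stratified cohort, take the 10% phenotypic
#' extremes, simulate ancestry SNPs for the retained subsample, compute
#' the top `n_pcs` principal-component scores of the standardized
#' genotype matrix, and test candidate-SNP association with extreme-group
#' status by logistic-regression likelihood-ratio tests with and/or
#' without the PC covariates.
#'
#' Two modes:
#' \describe{
#'   \item{`"balding_nichols"`}{Two equally mixed subpopulations; the
#'     candidate SNP is simulated separately (by default an extreme
#'     "A"-frequency contrast of 0.5 vs 0.9, or rare minor-allele
#'     frequencies via `candidate_mafs`); ancestry-SNP frequencies are
#'     re-drawn each replicate from the Balding-Nichols model.}
#'   \item{`"panel"`}{Four populations with phenotype means from the
#'     (synthetic) European frequency panel; the candidate SNP is chosen
#'     per replicate from the simulated panel SNPs by Fisher-exact
#'     differentiation screening ([select_confounded_candidate()]).}
#' }
#'
#' @param mode `"balding_nichols"` or `"panel"`.
#' @param mu1 Phenotype mean of population 1 (`mu2 = -mu1`);
#'   Balding-Nichols mode only.
#' @param candidate_mafs Optional length-2 minor-allele frequencies for a
#'   rare candidate SNP (Balding-Nichols mode), e.g. `c(0.01, 0.1)`.
#' @param models Genotype codings to test (`"codominant"`, `"additive"`).
#' @param adjust Which fits to run: `"unadjusted"`, `"adjusted"`, or both.
#' @param n_reps Replicates.
#' @param seed Root seed.
#' @param bn A [bn_params()] object for the ancestry SNPs
#'   (Balding-Nichols mode).
#' @param panel A `frequency_panel` (panel mode; default
#'   [synthetic_european_panel()] with 5,000 SNPs).
#' @param n_pcs Number of principal components (default 5).
#' @param candidate_threshold Differentiation threshold on `-log10(p)`
#'   for panel-mode candidate selection (default 4).
#' @return A data frame with one row per model x adjustment: replicate,
#'   rejection and invalid counts, `fpr` and `mc_se`.
#' @export
run_pc_correction_experiment <- function(mode = c("balding_nichols", "panel"),
                                         mu1 = 0.1, candidate_mafs = NULL,
                                         models = c("codominant", "additive"),
                                         adjust = c("unadjusted", "adjusted"),
                                         n_reps = 2000L, seed = 1L,
                                         bn = bn_params(),
                                         panel = NULL, n_pcs = 5L,
                                         candidate_threshold = 4) {
  mode <- match.arg(mode)
  models <- match.arg(models, c("codominant", "additive"), several.ok = TRUE)
  adjust <- match.arg(adjust, c("unadjusted", "adjusted"), several.ok = TRUE)
  params <- NULL; mu_vector <- NULL
  if (mode == "balding_nichols") {
    params <- if (is.null(candidate_mafs))
      scenario_params(omega1 = 0.5, mu1 = mu1, p1 = 0.5, p2 = 0.9)
    else
      preset_rare_variant(candidate_mafs[1], candidate_mafs[2],
                          omega1 = 0.5, mu1 = mu1)
  } else {
    if (is.null(panel)) panel <- synthetic_european_panel(5000L, seed = seed)
    mu_vector <- panel$phenotype_means
  }
  cells <- as.vector(outer(models, adjust, paste, sep = "."))
  rej <- inv <- stats::setNames(integer(length(cells)), cells)
  for (i in seq_len(n_reps)) {
    set.seed(replicate_seed(seed, i))
    r <- pc_correction_replicate(mode, params, mu_vector, bn, panel,
                                 models, adjust, n_pcs,
                                 candidate_threshold)
    inv[cells] <- inv[cells] + as.integer(is.na(r[cells]))
    rej[cells] <- rej[cells] + as.integer(!is.na(r[cells]) & r[cells])
  }
  do.call(rbind, lapply(cells, function(cl) {
    parts <- strsplit(cl, ".", fixed = TRUE)[[1]]
    fpr_row(paste0("pc_", mode), design = "eps", genetic_model = parts[1],
            test = paste0("logistic_lrt_", parts[2]), n_reps,
            rej[[cl]], inv[[cl]])
  }))
}

#' Write false-positive-rate estimates to disk
#'
#' Emits the long-format CSV (one row per estimate), a wide-format CSV
#' (designs x models spread into columns per scenario), and a JSON run
#' manifest carrying the root seed, package version and per-cell
#' Monte-Carlo standard errors, so a run can be reproduced bit-for-bit.
#'
#' @param estimates A data frame of estimates from the runners.
#' @param out_path Output directory (created if needed).
#' @param prefix File-name prefix (default `"fpr"`).
#' @param seed Root seed to record in the manifest.
#' @return Named character vector of the files written, invisibly.
#' @export
emit_tables <- function(estimates, out_path, prefix = "fpr", seed = NULL) {
  stopifnot(is.data.frame(estimates), nrow(estimates) > 0)
  if (!dir.exists(out_path))
    dir.create(out_path, recursive = TRUE)
  long_file <- file.path(out_path, paste0(prefix, "_long.csv"))
  utils::write.csv(estimates, long_file, row.names = FALSE)
  # spread design x model cells into columns; disambiguate with the test
  # label when several tests share a design x model cell (e.g. adjusted
  # and unadjusted logistic fits)
  est2 <- estimates
  est2$cell <- paste(est2$design, est2$genetic_model, sep = ".")
  key <- paste(est2$scenario, est2$cell)
  dup <- key %in% key[duplicated(key)]
  est2$cell[dup] <- paste(est2$cell[dup], est2$test[dup], sep = ".")
  wide <- stats::reshape(est2[, c("scenario", "cell", "fpr")],
                         idvar = "scenario", timevar = "cell",
                         direction = "wide", v.names = "fpr")
  names(wide) <- sub("^fpr\\.", "", names(wide))
  wide_file <- file.path(out_path, paste0(prefix, "_wide.csv"))
  utils::write.csv(wide, wide_file, row.names = FALSE)
  manifest <- list(
    seed = seed,
    package = "epsstrat",
    version = as.character(utils::packageVersion("epsstrat")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    n_estimates = nrow(estimates),
    cells = estimates[, c("scenario", "design", "genetic_model", "test",
                          "n_reps", "n_invalid", "fpr", "mc_se")])
  json_file <- file.path(out_path, paste0(prefix, "_manifest.json"))
  jsonlite::write_json(manifest, json_file, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(c(long = long_file, wide = wide_file, manifest = json_file))
}
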