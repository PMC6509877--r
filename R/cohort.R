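#' Simulate a stratified cohort under the null of no genetic effect
#'
#' Draws a cohort of `params$N` individuals from the two-subpopulation
#' mixture: subpopulation sizes are fixed at `round(omega1 * N)` and the
#' remainder (not binomial draws, which would only add Monte-Carlo
#' variance); phenotypes are normal within subpopulation
#' (`N(mu_i, sigma2)`); candidate-SNP genotypes are drawn from the
#' within-subpopulation Hardy-Weinberg probabilities. Phenotype and
#' genotype are drawn independently given the subpopulation, so the
#' candidate SNP has no causal effect.
#'
#' @param params A [scenario_params()] object.
#' @param seed Optional integer seed; when supplied the cohort is
#'   reproducible and the caller's RNG state is untouched.
#' @return A `cohort` object: list with numeric `phenotype`, integer
#'   `genotype` (0/1/2 copies of allele "a"), integer `population`
#'   (1 or 2) and the generating `params`.
#' @examples
#' ch <- simulate_cohort(scenario_params(omega1 = 0.3, N = 1000), seed = 1)
#' table(ch$population)
#' @export
simulate_cohort <- function(params, seed = NULL) {
  stopifnot(inherits(params, "scenario_params"))
  if (!is.null(seed)) return(with_seed(seed, simulate_cohort(params)))
  N <- params$N
  n1 <- as.integer(round(params$omega1 * N))
  n2 <- N - n1
  sizes <- c(n1, n2)
  s <- sqrt(params$sigma2)
  mu <- c(params$mu1, params$mu2)
  p <- c(params$p1, params$p2)
  phen <- geno <- vector("list", 2L)
  for (i in 1:2) {
    phen[[i]] <- stats::rnorm(sizes[i], mu[i], s)
    hwe <- c(p[i]^2, 2 * p[i] * (1 - p[i]), (1 - p[i])^2)
    geno[[i]] <- sample.int(3L, sizes[i], replace = TRUE, prob = hwe) - 1L
  }
  structure(
    list(phenotype = c(phen[[1]], phen[[2]]),
         genotype = c(geno[[1]], geno[[2]]),
         population = rep(1:2, sizes),
         params = params),
    class = "cohort")
}

#' Simulate a multi-population cohort from a frequency panel preset
#'
#' Generalization of [simulate_cohort()] to K subpopulations, used by the
#' four-population synthetic European panel experiment: equal (or given)
#' mixing proportions, per-population phenotype means with unit (or given)
#' variance, and an optional candidate SNP with per-population "a"-allele
#' minor frequencies `candidate_mafs`.
#'
#' @param N Cohort size.
#' @param phenotype_means Length-K vector of per-population means.
#' @param sigma2 Common within-population variance.
#' @param proportions Mixing proportions (default equal); must sum to 1.
#' @param candidate_mafs Optional length-K vector of candidate-SNP minor
#'   allele frequencies; when supplied, genotypes count the minor allele.
#' @param seed Optional integer seed.
#' @return A `cohort` object with `population` in `1..K` (and `genotype`
#'   `NA` when no candidate SNP is requested).
#' @export
simulate_multipop_cohort <- function(N, phenotype_means, sigma2 = 1,
                                     proportions = NULL,
                                     candidate_mafs = NULL, seed = NULL) {
  if (!is.null(seed))
    return(with_seed(seed, simulate_multipop_cohort(
      N, phenotype_means, sigma2, proportions, candidate_mafs)))
  K <- length(phenotype_means)
  if (is.null(proportions)) proportions <- rep(1 / K, K)
  stopifnot(length(proportions) == K, abs(sum(proportions) - 1) < 1e-8)
  sizes <- diff(round(cumsum(c(0, proportions)) * N))
  sizes <- as.integer(sizes)
  s <- sqrt(sigma2)
  phen <- unlist(lapply(seq_len(K), function(k)
    stats::rnorm(sizes[k], phenotype_means[k], s)))
  geno <- if (is.null(candidate_mafs)) rep(NA_integer_, sum(sizes)) else {
    stopifnot(length(candidate_mafs) == K)
    unlist(lapply(seq_len(K), function(k) {
      q <- candidate_mafs[k]
      hwe <- c((1 - q)^2, 2 * q * (1 - q), q^2)
      sample.int(3L, sizes[k], replace = TRUE, prob = hwe) - 1L
    }))
  }
  structure(
    list(phenotype = phen, genotype = geno,
         population = rep(seq_len(K), sizes), params = NULL),
    class = "cohort")
}

#' Dump a cohort as a tab-delimited table
#'
#' Debugging aid: writes columns `id`, `phenotype`, `genotype`,
#' `population`.
#'
#' @param cohort A `cohort` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  df <- data.frame(id = seq_along(cohort$phenotype),
                   phenotype = cohort$phenotype,
                   genotype = cohort$genotype,
                   population = cohort$population)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
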