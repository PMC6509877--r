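#' Simulation scenario parameters
#'
#' Bundles every quantity that defines one stratified-cohort scenario: a
#' cohort of `N` individuals is a mixture of two hidden subpopulations in
#' proportions `omega1` and `1 - omega1`; the phenotype is normal within
#' each subpopulation with means `mu1`, `mu2` and common variance `sigma2`;
#' the candidate SNP has "A"-allele frequency `p1` and `p2` in the two
#' subpopulations with Hardy-Weinberg genotype frequencies within each.
#' Genotype and phenotype are independent given the subpopulation, so any
#' association in a subsample is spurious (confounding by ancestry).
#'
#' @param omega1 Proportion of the cohort from subpopulation 1, in (0, 1).
#' @param mu1,mu2 Phenotype means in subpopulations 1 and 2 (phenotype
#'   units). `mu2` defaults to `-mu1`, the symmetric convention used
#'   throughout the two-population experiments, but can be set freely (the
#'   Italy/France preset uses raw height means).
#' @param sigma2 Common within-subpopulation phenotype variance (> 0).
#' @param p1,p2 Frequency of the "A" allele of the candidate SNP in
#'   subpopulations 1 and 2, each in \[0, 1\]. Genotypes are coded as the
#'   count of the "a" allele, so 0 = AA, 1 = Aa, 2 = aa.
#' @param N Cohort size (number of phenotyped individuals).
#' @param tail_fraction Fraction of the cohort genotyped per phenotypic
#'   extreme; the per-tail sample size is `n = round(tail_fraction * N)`.
#'   Must lie in (0, 0.25\].
#' @param alpha Nominal significance level for all association tests.
#'
#' @return An object of class `scenario_params` (a named list with the
#'   fields above plus the derived `omega2` and per-tail `n`).
#' @examples
#' sp <- scenario_params(omega1 = 0.3, mu1 = 0.1, p1 = 0.5, p2 = 0.7)
#' sp$n   # 500 individuals per extreme
#' @export
scenario_params <- function(omega1 = 0.5, mu1 = 0.1, mu2 = -mu1,
                            sigma2 = 1, p1 = 0.5, p2 = 0.5,
                            N = 5000L, tail_fraction = 0.1, alpha = 0.05) {
  stopifnot(is.numeric(omega1), length(omega1) == 1L,
            is.numeric(mu1), is.numeric(mu2), is.numeric(sigma2),
            is.numeric(p1), is.numeric(p2), is.numeric(N),
            is.numeric(tail_fraction), is.numeric(alpha))
  if (!(omega1 > 0 && omega1 < 1))
    stop("`omega1` must lie strictly in (0, 1)", call. = FALSE)
  if (p1 < 0 || p1 > 1 || p2 < 0 || p2 > 1)
    stop("allele frequencies `p1`, `p2` must lie in [0, 1]", call. = FALSE)
  if (sigma2 <= 0) stop("`sigma2` must be positive", call. = FALSE)
  if (!(tail_fraction > 0 && tail_fraction <= 0.25))
    stop("`tail_fraction` must lie in (0, 0.25]", call. = FALSE)
  if (N < 2) stop("`N` must be at least 2", call. = FALSE)
  if (!(alpha > 0 && alpha < 1))
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  structure(
    list(omega1 = omega1, omega2 = 1 - omega1,
         mu1 = mu1, mu2 = mu2, sigma2 = sigma2,
         p1 = p1, p2 = p2, N = as.integer(round(N)),
         tail_fraction = tail_fraction,
         n = as.integer(round(tail_fraction * N)),
         alpha = alpha),
    class = "scenario_params")
}

#' @export
print.scenario_params <- function(x, ...) {
  cat("Two-subpopulation stratification scenario\n")
  cat(sprintf("  mixing        omega1 = %.3g, omega2 = %.3g\n", x$omega1, x$omega2))
  cat(sprintf("  phenotype     mu1 = %.4g, mu2 = %.4g, sigma2 = %.3g\n",
              x$mu1, x$mu2, x$sigma2))
  cat(sprintf("  candidate SNP p1 = %.3g, p2 = %.3g (freq. of allele A)\n",
              x$p1, x$p2))
  cat(sprintf("  sampling      N = %d, tail fraction %.3g (n = %d per extreme), alpha = %.3g\n",
              x$N, x$tail_fraction, x$n, x$alpha))
  invisible(x)
}

#' European-data preset: lactase-variant frequencies, female height
#'
#' Scenario parameterized from published European data: candidate-SNP
#' "A"-allele frequencies of the lactose-tolerance variant in Italy (0.286)
#' and France (0.43), and female mean height of 158.48 cm (Italy) and
#' 161.77 cm (France) with common variance 6 cm^2. Population 1 is Italy.
#'
#' @param omega1 Proportion of the cohort from Italy (default 0.5).
#' @param N Cohort size (default 5000).
#' @param tail_fraction Fraction genotyped per extreme (default 0.1).
#' @param alpha Significance level (default 0.05).
#' @return A [scenario_params()] object.
#' @examples
#' preset_italy_france()$p1   # 0.286
#' @export
preset_italy_france <- function(omega1 = 0.5, N = 5000L,
                                tail_fraction = 0.1, alpha = 0.05) {
  scenario_params(omega1 = omega1,
                  mu1 = 158.48, mu2 = 161.77, sigma2 = 6,
                  p1 = 0.286, p2 = 0.43,
                  N = N, tail_fraction = tail_fraction, alpha = alpha)
}

#' Rare/low-frequency candidate-SNP preset
#'
#' Scenario where the candidate SNP's minor allele ("a") has frequency
#' `maf1` in subpopulation 1 and `maf2` in subpopulation 2 (the study grid
#' pairs 0.01 with 0.01, 0.05 or 0.10). Since genotypes count the "a"
#' allele and `p` is the "A" frequency, `p_i = 1 - maf_i`.
#'
#' @param maf1,maf2 Minor-allele frequencies in (0, 0.5].
#' @param omega1,mu1,mu2,sigma2,N,tail_fraction,alpha As in
#'   [scenario_params()].
#' @return A [scenario_params()] object.
#' @export
preset_rare_variant <- function(maf1 = 0.01, maf2 = 0.05,
                                omega1 = 0.5, mu1 = 0.1, mu2 = -mu1,
                                sigma2 = 1, N = 5000L,
                                tail_fraction = 0.1, alpha = 0.05) {
  if (maf1 <= 0 || maf1 > 0.5 || maf2 <= 0 || maf2 > 0.5)
    stop("minor allele frequencies must lie in (0, 0.5]", call. = FALSE)
  scenario_params(omega1 = omega1, mu1 = mu1, mu2 = mu2, sigma2 = sigma2,
                  p1 = 1 - maf1, p2 = 1 - maf2,
                  N = N, tail_fraction = tail_fraction, alpha = alpha)
}
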