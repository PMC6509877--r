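# Closed-form mathematics of the two-subpopulation mixture model.
# Genotype classes are ordered (AA, Aa, aa) = 0, 1, 2 copies of allele "a".

GENOTYPE_CLASSES <- c("AA", "Aa", "aa")

#' Marginal genotype probabilities in the mixed cohort
#'
#' Under Hardy-Weinberg equilibrium within each subpopulation, the
#' cohort-level genotype probabilities are the mixture
#' \deqn{p_{AA} = \omega_1 p_1^2 + \omega_2 p_2^2,\quad
#'       p_{Aa} = 2\omega_1 p_1(1-p_1) + 2\omega_2 p_2(1-p_2),\quad
#'       p_{aa} = \omega_1(1-p_1)^2 + \omega_2(1-p_2)^2.}
#' HWE holds within each subpopulation by construction but generally not
#' in the mixture (the Wahlund effect).
#'
#' @param params A [scenario_params()] object.
#' @return Named numeric vector `c(AA=, Aa=, aa=)` summing to 1.
#' @examples
#' genotype_probabilities(scenario_params(omega1 = 0.5, p1 = 0.5, p2 = 0.9))
#' @export
genotype_probabilities <- function(params) {
  stopifnot(inherits(params, "scenario_params"))
  w <- c(params$omega1, params$omega2)
  p <- c(params$p1, params$p2)
  out <- c(AA = sum(w * p^2),
           Aa = sum(w * 2 * p * (1 - p)),
           aa = sum(w * (1 - p)^2))
  out
}

#' Cohort-level phenotype CDF
#'
#' The phenotype marginal over subpopulations is the two-component normal
#' mixture \eqn{F(y) = \omega_1\Phi((y-\mu_1)/\sigma) +
#' \omega_2\Phi((y-\mu_2)/\sigma)}.
#'
#' @param y Numeric vector of phenotype values.
#' @param params A [scenario_params()] object.
#' @return Probabilities `F(y)`, same length as `y`.
#' @export
mixture_cdf <- function(y, params) {
  stopifnot(inherits(params, "scenario_params"))
  s <- sqrt(params$sigma2)
  params$omega1 * stats::pnorm(y, params$mu1, s) +
    params$omega2 * stats::pnorm(y, params$mu2, s)
}

#' Cohort-level phenotype quantile
#'
#' Numeric inverse of [mixture_cdf()], used for analytic tail thresholds.
#' Root-bracketed between the component quantiles and solved to machine-
#' level tolerance.
#'
#' @param q Probabilities in (0, 1) (vectorized).
#' @param params A [scenario_params()] object.
#' @return Phenotype values `y` with `mixture_cdf(y) = q`.
#' @export
mixture_quantile <- function(q, params) {
  stopifnot(inherits(params, "scenario_params"))
  if (any(q <= 0 | q >= 1))
    stop("`q` must lie strictly in (0, 1)", call. = FALSE)
  s <- sqrt(params$sigma2)
  vapply(q, function(qi) {
    br <- range(stats::qnorm(qi, params$mu1, s),
                stats::qnorm(qi, params$mu2, s))
    if (br[1] == br[2]) return(br[1])
    stats::uniroot(function(y) mixture_cdf(y, params) - qi,
                   interval = br, extendInt = "upX",
                   tol = 1e-12)$root
  }, numeric(1))
}

#' Probability of subpopulation membership given candidate genotype
#'
#' Bayes' rule on the mixture genotype probabilities: for genotype class
#' g, \eqn{\Pr(i=1 \mid g) = \omega_1 \Pr(g \mid i=1) / \Pr(g)}. When
#' `p1 = p2` the genotype carries no ancestry information and every entry
#' equals `omega1`.
#'
#' @param params A [scenario_params()] object.
#' @return Named numeric vector `c(AA=, Aa=, aa=)` of `Pr(pop 1 | g)`.
#' @export
population_given_genotype <- function(params) {
  stopifnot(inherits(params, "scenario_params"))
  p1 <- params$p1
  num <- params$omega1 * c(AA = p1^2, Aa = 2 * p1 * (1 - p1), aa = (1 - p1)^2)
  den <- genotype_probabilities(params)
  if (any(den == 0))
    stop("conditional membership undefined: genotype class ",
         paste(names(den)[den == 0], collapse = ", "),
         " has zero marginal probability", call. = FALSE)
  num / den
}

#' Phenotype CDF conditional on candidate genotype
#'
#' Under the null of no causal effect, phenotype depends on genotype only
#' through ancestry: \eqn{F(y \mid g) = p_{1|g}\,\Phi((y-\mu_1)/\sigma) +
#' p_{2|g}\,\Phi((y-\mu_2)/\sigma)} with the membership weights from
#' [population_given_genotype()]. This dependence is the entire source of
#' spurious association in the study.
#'
#' @param y Numeric vector of phenotype values.
#' @param g Genotype class: one of `"AA"`, `"Aa"`, `"aa"` (or 0/1/2 counts
#'   of allele "a").
#' @param params A [scenario_params()] object.
#' @return Probabilities `F(y | g)`, same length as `y`.
#' @export
phenotype_cdf_given_genotype <- function(y, g, params) {
  stopifnot(inherits(params, "scenario_params"))
  if (is.numeric(g)) g <- GENOTYPE_CLASSES[g + 1L]
  g <- match.arg(g, GENOTYPE_CLASSES)
  w1 <- population_given_genotype(params)[[g]]
  s <- sqrt(params$sigma2)
  w1 * stats::pnorm(y, params$mu1, s) +
    (1 - w1) * stats::pnorm(y, params$mu2, s)
}

# Genotype distribution within each phenotypic tail:
#   Pr(g | Y <= t_lo) = Pr(g) F(t_lo | g) / tail_fraction,
#   Pr(g | Y >  t_hi) = Pr(g) (1 - F(t_hi | g)) / tail_fraction.
# Returns a list with per-tail genotype probability vectors (AA, Aa, aa).
tail_genotype_probs <- function(params) {
  tf <- params$tail_fraction
  t_lo <- mixture_quantile(tf, params)
  t_hi <- mixture_quantile(1 - tf, params)
  pg <- genotype_probabilities(params)
  F_lo <- vapply(GENOTYPE_CLASSES, function(g)
    phenotype_cdf_given_genotype(t_lo, g, params), numeric(1))
  F_hi <- vapply(GENOTYPE_CLASSES, function(g)
    phenotype_cdf_given_genotype(t_hi, g, params), numeric(1))
  lo <- pg * F_lo / tf
  hi <- pg * (1 - F_hi) / tf
  # guard tiny negative rounding and renormalize the O(1e-12) slack
  lo <- pmax(lo, 0) / sum(pmax(lo, 0))
  hi <- pmax(hi, 0) / sum(pmax(hi, 0))
  list(lower = lo, upper = hi, t_lo = t_lo, t_hi = t_hi)
}

#' Analytic large-sample false positive rate under extreme sampling
#'
#' Computes, without simulation, the probability that the association test
#' for the given genetic model rejects at level `alpha` when the upper and
#' lower `tail_fraction` extremes of the cohort are contrasted, under the
#' null of no causal genotype effect. The route: tail thresholds from
#' [mixture_quantile()]; genotype distributions within each tail from
#' [phenotype_cdf_given_genotype()] via Bayes' rule; then the asymptotic
#' distribution of the test statistic for two independent samples of size
#' `n` per tail drawn from those genotype distributions:
#' \itemize{
#'   \item additive (Cochran-Armitage trend) and recessive (pooled
#'     two-proportion z): normal with mean equal to the statistic's drift
#'     and the exact large-sample variance under the induced alternative
#'     (not unity, because the pooled null variance estimate converges to
#'     the mixture variance);
#'   \item codominant (2-df Pearson chi-square): noncentral chi-square
#'     with \eqn{\lambda = n \sum_g (p_{hi,g}-p_{lo,g})^2 /
#'     (p_{hi,g}+p_{lo,g})}.
#' }
#' Genotype classes with zero probability in both tails are dropped and
#' the degrees of freedom reduced accordingly.
#'
#' When `p1 = p2` or `mu1 = mu2` there is no confounding and the function
#' returns `alpha` exactly.
#'
#' @param params A [scenario_params()] object.
#' @param genetic_model One of `"codominant"`, `"additive"`, `"recessive"`.
#' @return Rejection probability in \[0, 1\].
#' @examples
#' sp <- scenario_params(omega1 = 0.3, mu1 = 0.1, p1 = 0.5, p2 = 0.7)
#' analytic_eps_fpr(sp, "additive")   # far above the nominal 0.05
#' @export
analytic_eps_fpr <- function(params,
                             genetic_model = c("codominant", "additive",
                                               "recessive")) {
  stopifnot(inherits(params, "scenario_params"))
  genetic_model <- match.arg(genetic_model)
  tp <- tail_genotype_probs(params)
  p_lo <- tp$lower; p_hi <- tp$upper
  n <- params$n
  alpha <- params$alpha

  if (genetic_model == "codominant") {
    keep <- (p_lo + p_hi) > 0
    if (sum(keep) < 2) return(0)  # degenerate: single genotype class
    lam <- n * sum((p_hi[keep] - p_lo[keep])^2 / (p_hi[keep] + p_lo[keep]))
    df <- sum(keep) - 1L
    crit <- stats::qchisq(1 - alpha, df)
    return(stats::pchisq(crit, df, ncp = lam, lower.tail = FALSE))
  }

  if (genetic_model == "additive") {
    s <- 0:2
    delta <- sum(s * (p_hi - p_lo))
    v_hi <- sum(s^2 * p_hi) - sum(s * p_hi)^2
    v_lo <- sum(s^2 * p_lo) - sum(s * p_lo)^2
    pbar <- (p_hi + p_lo) / 2
    v_pool <- sum(s^2 * pbar) - sum(s * pbar)^2  # incl. between-tail spread
    if (v_pool <= 0) return(0)
    m <- delta * sqrt(n / (2 * v_pool))
    sd_alt <- sqrt((v_hi + v_lo) / (2 * v_pool))
  } else { # recessive: aa vs AA+Aa
    q_hi <- p_hi[["aa"]]; q_lo <- p_lo[["aa"]]
    qbar <- (q_hi + q_lo) / 2
    if (qbar <= 0 || qbar >= 1) return(0)
    m <- (q_hi - q_lo) * sqrt(n / (2 * qbar * (1 - qbar)))
    sd_alt <- sqrt((q_hi * (1 - q_hi) + q_lo * (1 - q_lo)) /
                     (2 * qbar * (1 - qbar)))
  }
  zc <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(-zc, mean = m, sd = sd_alt) +
    stats::pnorm(zc, mean = m, sd = sd_alt, lower.tail = FALSE)
}
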