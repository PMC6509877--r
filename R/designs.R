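# The three subsampling designs compared in the study. Each returns a
# `design_sample`: genotype (0/1/2), binary `group` (1 = upper extreme /
# case, 0 = lower extreme / control; NA for the random design), retained
# `phenotype`, and `indices` into the source cohort.

design_sample <- function(design, cohort, idx, group) {
  structure(
    list(design = design,
         genotype = cohort$genotype[idx],
         phenotype = cohort$phenotype[idx],
         group = group,
         indices = idx),
    class = "design_sample")
}

#' Extreme phenotype sample (upper and lower tails)
#'
#' Rank-based selection of exactly the `n` lowest and `n` highest
#' phenotype values (ties broken by stable storage order). The lower
#' extreme is coded `group = 0`, the upper `group = 1`.
#'
#' @param cohort A `cohort` object.
#' @param n Individuals per extreme; `2n` must not exceed the cohort size.
#' @return A `design_sample`.
#' @export
eps_sample <- function(cohort, n) {
  stopifnot(inherits(cohort, "cohort"))
  N <- length(cohort$phenotype)
  if (2 * n > N) stop("2n exceeds cohort size", call. = FALSE)
  ord <- order(cohort$phenotype)  # stable for ties
  idx <- c(ord[seq_len(n)], ord[seq.int(N - n + 1L, N)])
  design_sample("eps", cohort, idx, group = rep(0:1, each = n))
}

#' Simple random sample retaining the continuous phenotype
#'
#' @param cohort A `cohort` object.
#' @param m Sample size (without replacement).
#' @return A `design_sample` with `group = NA` (the random design is
#'   analyzed on the quantitative phenotype).
#' @export
random_sample <- function(cohort, m) {
  stopifnot(inherits(cohort, "cohort"))
  N <- length(cohort$phenotype)
  if (m > N) stop("sample size exceeds cohort size", call. = FALSE)
  idx <- sample.int(N, m)
  design_sample("random", cohort, idx, group = rep(NA_integer_, m))
}

#' Case-control-like sample: top extreme vs random controls
#'
#' Cases are the `n` highest phenotype values (as if disease status were a
#' quantitative variable exceeding a threshold); controls are `n`
#' individuals drawn uniformly without replacement from the remaining
#' `N - n`.
#'
#' @param cohort A `cohort` object.
#' @param n Number of cases (= number of controls).
#' @return A `design_sample` with `group = 1` for cases, `0` for controls.
#' @export
case_control_sample <- function(cohort, n) {
  stopifnot(inherits(cohort, "cohort"))
  N <- length(cohort$phenotype)
  if (2 * n > N) stop("2n exceeds cohort size", call. = FALSE)
  # decreasing stable order: under complete ties the cases are the first n
  # individuals in storage order (documented degenerate behavior)
  ord <- order(cohort$phenotype, decreasing = TRUE)
  cases <- ord[seq_len(n)]
  rest <- ord[seq.int(n + 1L, N)]
  controls <- rest[sample.int(N - n, n)]
  design_sample("case_control", cohort, c(controls, cases),
                group = rep(0:1, each = n))
}
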