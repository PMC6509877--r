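# Ancestry-SNP simulation (Balding-Nichols and frequency-panel modes),
# EIGENSTRAT-style genotype standardization, principal-component scores,
# and Fisher-exact selection of a stratification-confounded candidate SNP.

#' Balding-Nichols simulation settings
#'
#' @param n_snps Number of ancestry SNPs (default 5000).
#' @param fst Fixation index governing between-population differentiation,
#'   in (0, 1) (default 0.01, higher than typical intra-European values).
#' @param ancestral_freq_range Interval from which each SNP's generating
#'   ("ancestral") allele frequency is drawn uniformly (default 0.1-0.9).
#' @return A `bn_params` list. The per-population frequency of a SNP with
#'   generating frequency `p` is Beta with shape parameters
#'   `a_shape = p (1 - fst) / fst` and `b_shape = (1 - p)(1 - fst) / fst`
#'   (so mean `p` and variance `p (1 - p) fst`).
#' @export
bn_params <- function(n_snps = 5000L, fst = 0.01,
                      ancestral_freq_range = c(0.1, 0.9)) {
  if (!(fst > 0 && fst < 1)) stop("`fst` must lie in (0, 1)", call. = FALSE)
  stopifnot(n_snps >= 1, length(ancestral_freq_range) == 2,
            ancestral_freq_range[1] > 0, ancestral_freq_range[2] < 1,
            ancestral_freq_range[1] <= ancestral_freq_range[2])
  structure(list(n_snps = as.integer(n_snps), fst = fst,
                 ancestral_freq_range = ancestral_freq_range),
            class = "bn_params")
}

new_frequency_panel <- function(pop_labels, freqs, phenotype_means = NULL,
                                candidate_mafs = NULL) {
  stopifnot(ncol(freqs) == length(pop_labels))
  colnames(freqs) <- pop_labels
  structure(list(pop_labels = pop_labels, freqs = freqs,
                 phenotype_means = phenotype_means,
                 candidate_mafs = candidate_mafs),
            class = "frequency_panel")
}

#' Draw per-population allele frequencies under the Balding-Nichols model
#'
#' For each SNP a generating frequency `p` is drawn uniformly from
#' `ancestral_freq_range`, then each population's frequency is an
#' independent Beta(`p(1-fst)/fst`, `(1-p)(1-fst)/fst`) draw.
#'
#' @param params A [bn_params()] object.
#' @param n_pops Number of populations (default 2).
#' @param seed Optional integer seed.
#' @return A `frequency_panel`: SNPs x populations frequency matrix.
#' @export
balding_nichols_freqs <- function(params = bn_params(), n_pops = 2L,
                                  seed = NULL) {
  stopifnot(inherits(params, "bn_params"))
  if (!is.null(seed))
    return(with_seed(seed, balding_nichols_freqs(params, n_pops)))
  m <- params$n_snps
  p <- stats::runif(m, params$ancestral_freq_range[1],
                    params$ancestral_freq_range[2])
  ratio <- (1 - params$fst) / params$fst
  freqs <- matrix(stats::rbeta(m * n_pops, rep(p * ratio, n_pops),
                               rep((1 - p) * ratio, n_pops)),
                  nrow = m, ncol = n_pops)
  panel <- new_frequency_panel(paste0("pop", seq_len(n_pops)), freqs)
  panel$ancestral_freq <- p
  panel
}

#' Synthetic four-population European-like allele-frequency panel
#'
#' Stands in for a real reference panel of common European SNPs (labelled
#' TSI, IBS, GBR, FIN). Differentiation is heterogeneous across SNPs: each
#' SNP's own Fst is drawn from a two-component mixture (by default 95%
#' mass around 0.004 and 5% around 0.05), so most SNPs differ little
#' between populations while a minority differ substantially. Retained
#' SNPs satisfy the reference-data filters by construction: overall minor
#' allele frequency > 0.05, minor allele present in every population, and
#' maximum per-population allele frequency at least 0.1. This panel is
#' synthetic; its marginal frequency spectrum, not any real genotype data,
#' emulates a filtered European reference set.
#'
#' @param n_snps Number of SNPs to retain (default 20000; scale up or down
#'   freely).
#' @param seed Optional integer seed.
#' @param fst_low,fst_high Mean per-SNP Fst of the two mixture components.
#' @param prop_high Proportion of highly differentiated SNPs.
#' @return A `frequency_panel` with `phenotype_means = c(0.3, 0.2, 0,
#'   -0.1)` (TSI, IBS, GBR, FIN) and rare-candidate preset
#'   `candidate_mafs = c(0.01, 0.02, 0.05, 0.1)`.
#' @export
synthetic_european_panel <- function(n_snps = 20000L, seed = NULL,
                                     fst_low = 0.004, fst_high = 0.05,
                                     prop_high = 0.05) {
  if (!is.null(seed))
    return(with_seed(seed, synthetic_european_panel(
      n_snps, NULL, fst_low, fst_high, prop_high)))
  labels <- c("TSI", "IBS", "GBR", "FIN")
  K <- 4L
  kept <- matrix(numeric(0), ncol = K)
  min_obs <- 1 / 200  # minor allele must be observable in a modest sample
  while (nrow(kept) < n_snps) {
    m <- max(2L * (n_snps - nrow(kept)), 1000L)
    p <- stats::runif(m, 0.1, 0.9)
    fst <- ifelse(stats::runif(m) < prop_high,
                  stats::rgamma(m, shape = 4, rate = 4 / fst_high),
                  stats::rgamma(m, shape = 4, rate = 4 / fst_low))
    fst <- pmin(pmax(fst, 1e-4), 0.5)
    ratio <- (1 - fst) / fst
    f <- matrix(stats::rbeta(m * K, rep(p * ratio, K),
                             rep((1 - p) * ratio, K)), nrow = m)
    maf_overall <- pmin(rowMeans(f), 1 - rowMeans(f))
    ok <- maf_overall > 0.05 &
      apply(f, 1, function(x) all(pmin(x, 1 - x) >= min_obs)) &
      apply(f, 1, max) >= 0.1
    kept <- rbind(kept, f[ok, , drop = FALSE])
  }
  kept <- kept[seq_len(n_snps), , drop = FALSE]
  new_frequency_panel(labels, kept,
                      phenotype_means = c(TSI = 0.3, IBS = 0.2,
                                          GBR = 0, FIN = -0.1),
                      candidate_mafs = c(TSI = 0.01, IBS = 0.02,
                                         GBR = 0.05, FIN = 0.1))
}

#' Read/write a frequency panel as tab-delimited text
#'
#' Columns: `snp` identifier then one allele-frequency column per
#' population, so real allele-frequency tables can be substituted.
#'
#' @param panel A `frequency_panel`.
#' @param path File path.
#' @return `write_frequency_panel()` returns `path` invisibly;
#'   `read_frequency_panel()` returns a `frequency_panel`.
#' @export
write_frequency_panel <- function(panel, path) {
  stopifnot(inherits(panel, "frequency_panel"))
  df <- data.frame(snp = seq_len(nrow(panel$freqs)), panel$freqs,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frequency_panel
#' @export
read_frequency_panel <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  new_frequency_panel(colnames(df)[-1],
                      as.matrix(df[, -1, drop = FALSE]))
}

#' Simulate ancestry-SNP genotypes from a frequency panel
#'
#' Each individual's genotype at each SNP is an independent
#' Binomial(2, f) draw, where `f` is the panel frequency of the "1"
#' allele for that individual's population (Hardy-Weinberg within
#' population).
#'
#' @param panel A `frequency_panel`.
#' @param pop_of_individual Vector of population labels (or 1-based
#'   indices into `panel$pop_labels`), one per individual.
#' @param seed Optional integer seed.
#' @return Integer matrix, individuals x SNPs, of 0/1/2 counts.
#' @export
simulate_panel_genotypes <- function(panel, pop_of_individual, seed = NULL) {
  stopifnot(inherits(panel, "frequency_panel"))
  if (!is.null(seed))
    return(with_seed(seed, simulate_panel_genotypes(panel, pop_of_individual)))
  if (is.numeric(pop_of_individual)) {
    k <- as.integer(pop_of_individual)
    if (any(k < 1 | k > length(panel$pop_labels)))
      stop("population index out of range", call. = FALSE)
  } else {
    k <- match(as.character(pop_of_individual), panel$pop_labels)
    if (anyNA(k)) stop("unknown population label", call. = FALSE)
  }
  .panel_genotypes_cpp(panel$freqs, k)
}

#' Standardize a genotype matrix for principal-component analysis
#'
#' Each SNP column is centered at its mean and divided by
#' \eqn{\sqrt{\tilde p (1 - \tilde p)}}, where
#' \eqn{\tilde p = (1 + \sum_k g_k) / (2 + 2n)} is the pseudo-count
#' estimate of the "1"-allele frequency over the `n` individuals in the
#' subsample. The pseudo-count keeps the scale strictly positive, so
#' monomorphic columns are retained (as all-zero columns after centering).
#'
#' @param genotypes Individuals x SNPs matrix of 0/1/2 counts.
#' @return List with `standardized` (numeric matrix, columns mean-zero)
#'   and `est_freq` (per-SNP \eqn{\tilde p}).
#' @export
standardize_genotypes <- function(genotypes) {
  if (!is.integer(genotypes)) storage.mode(genotypes) <- "integer"
  .standardize_cpp(genotypes)
}

#' Top principal-component scores of a standardized genotype matrix
#'
#' Returns the scores (left singular vectors scaled by singular values) of
#' the top `k` principal components. Small problems use an exact SVD; for
#' larger matrices a randomized range-finder with power iterations (Halko
#' et al. subspace iteration, oversampling 10, `q = 4`) computes the top
#' components to working accuracy at a fraction of the cost of a full
#' decomposition. The sign of each component is arbitrary.
#'
#' @param standardized Numeric matrix (individuals x SNPs), columns
#'   centered.
#' @param k Number of components (default 5).
#' @param exact Force the exact SVD branch (default: exact when the
#'   smaller matrix dimension is at most 300).
#' @return Numeric matrix, individuals x `k`, of PC scores; columns are
#'   orthogonal with nonincreasing variance.
#' @export
compute_pcs <- function(standardized, k = 5L, exact = NULL) {
  n <- nrow(standardized); m <- ncol(standardized)
  if (n < 2) stop("need more than one individual", call. = FALSE)
  if (k > min(n, m)) stop("`k` exceeds matrix rank bound", call. = FALSE)
  if (is.null(exact)) exact <- min(n, m) <= 300
  if (exact) {
    sv <- svd(standardized, nu = min(n, m), nv = 0)
    return(sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k))
  }
  l <- min(k + 10L, min(n, m))
  Omega <- matrix(stats::rnorm(m * l), m, l)
  Y <- standardized %*% Omega
  for (it in 1:4) {
    Y <- qr.Q(qr(Y))
    Y <- standardized %*% crossprod(standardized, Y)
  }
  Q <- qr.Q(qr(Y))
  B <- crossprod(Q, standardized)        # l x m
  sb <- svd(B, nu = l, nv = 0)
  scores <- (Q %*% sb$u)[, seq_len(k), drop = FALSE]
  scores %*% diag(sb$d[seq_len(k)], k)
}

#' Select a stratification-confounded candidate SNP
#'
#' Tests each SNP for unequal allele frequencies across populations with a
#' Fisher exact test on the 2 x K allele-count table built from the
#' sampled genotypes, and returns one SNP chosen uniformly among those
#' with `-log10(p)` above `threshold`. For K = 2 the exact test is used
#' directly; for K > 2 a chi-square screen is followed by Fisher tests
#' with a simulated null (B = 19,999 tables), whose resolution
#' (`p >= 1/(B+1) = 5e-5`) is finer than the default threshold of 4.
#'
#' @param genotypes Individuals x SNPs matrix of 0/1/2 counts.
#' @param pop_labels Population label per individual (>= 2 populations).
#' @param threshold Minimum `-log10(p)` (default 4).
#' @return Integer SNP (column) index. Errors with class
#'   `epsstrat_no_candidate` if no SNP exceeds the threshold (regenerate
#'   the panel or lower the threshold).
#' @export
select_confounded_candidate <- function(genotypes, pop_labels,
                                        threshold = 4) {
  pop <- factor(pop_labels)
  if (nlevels(pop) < 2)
    stop("need at least two populations", call. = FALSE)
  sizes <- tabulate(pop)
  # allele-count table per SNP: "1" alleles and "0" alleles per population
  ones <- rowsum(genotypes, pop)                 # K x SNPs count of "1"
  zeros <- 2 * sizes - ones
  # chi-square screen (upper bound shortlist), then exact/simulated Fisher
  chi_p <- vapply(seq_len(ncol(genotypes)), function(j) {
    tab <- rbind(ones[, j], zeros[, j])
    if (any(colSums(tab) == 0) || any(rowSums(tab) == 0)) return(1)
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  }, numeric(1))
  shortlist <- which(chi_p < 10^(-max(threshold - 2, 0)))
  if (length(shortlist) == 0)
    stop(structure(class = c("epsstrat_no_candidate", "error", "condition"),
                   list(message = "no SNP exceeds the differentiation threshold; regenerate the panel",
                        call = sys.call())))
  fisher_p <- vapply(shortlist, function(j) {
    tab <- rbind(ones[, j], zeros[, j])
    if (nlevels(pop) == 2)
      stats::fisher.test(tab)$p.value
    else
      stats::fisher.test(tab, simulate.p.value = TRUE, B = 19999)$p.value
  }, numeric(1))
  hits <- shortlist[-log10(fisher_p) > threshold]
  if (length(hits) == 0)
    stop(structure(class = c("epsstrat_no_candidate", "error", "condition"),
                   list(message = "no SNP exceeds the differentiation threshold; regenerate the panel",
                        call = sys.call())))
  hits[sample.int(length(hits), 1L)]
}
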