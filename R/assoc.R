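# Single-SNP association tests, one per (design x genetic model) cell.
# Every test returns a `test_result`: statistic, df (NA if none), p_value,
# valid flag (FALSE with a reason code for degenerate inputs), and labels.
# No continuity corrections anywhere, so the z^2 = chi-square identity on
# 2x2 tables is exact and the rates match the asymptotic tests the study
# design implies. Invalid results are counted as non-rejections upstream.

test_result <- function(test_name, genetic_model, statistic = NA_real_,
                        df = NA_real_, p_value = NA_real_,
                        valid = TRUE, reason = NA_character_) {
  structure(list(test_name = test_name, genetic_model = genetic_model,
                 statistic = statistic, df = df, p_value = p_value,
                 valid = valid, reason = reason),
            class = "test_result")
}

#' Cross-classify a binary-group sample by genotype
#'
#' Builds the contingency table for a binary-group design sample: rows are
#' the groups (row 1 = group 0, row 2 = group 1), columns the genotype
#' categories of the genetic model — `(AA, Aa, aa)` for codominant and
#' additive (the additive table carries scores 0, 1, 2 as an attribute),
#' `(AA+Aa, aa)` for recessive.
#'
#' @param sample A `design_sample` with non-missing binary `group`.
#' @param genetic_model One of `"codominant"`, `"additive"`, `"recessive"`.
#' @return Integer matrix (2 x 3 or 2 x 2); additive tables have a
#'   `scores` attribute.
#' @export
build_table <- function(sample,
                        genetic_model = c("codominant", "additive",
                                          "recessive")) {
  stopifnot(inherits(sample, "design_sample"))
  genetic_model <- match.arg(genetic_model)
  if (anyNA(sample$group))
    stop("sample has no binary group labels (random design?)", call. = FALSE)
  g <- factor(sample$genotype, levels = 0:2, labels = GENOTYPE_CLASSES)
  tab <- table(factor(sample$group, levels = 0:1), g)
  tab <- matrix(as.integer(tab), nrow = 2,
                dimnames = list(group = c("0", "1"), genotype = GENOTYPE_CLASSES))
  if (genetic_model == "recessive") {
    tab <- cbind(`AA+Aa` = tab[, "AA"] + tab[, "Aa"], aa = tab[, "aa"])
  } else if (genetic_model == "additive") {
    attr(tab, "scores") <- 0:2
  }
  tab
}

#' Pearson chi-square test of genotype-group independence
#'
#' Classical Pearson statistic on a 2 x C table, no continuity correction.
#' All-zero genotype columns are dropped and the degrees of freedom reduced
#' to (number of non-empty columns - 1); fewer than two non-empty columns
#' yields `valid = FALSE`.
#'
#' @param table Integer matrix with 2 rows (groups) and genotype columns.
#' @return A `test_result`.
#' @export
pearson_chisq <- function(table) {
  keep <- colSums(table) > 0
  tab <- table[, keep, drop = FALSE]
  if (ncol(tab) < 2 || any(rowSums(tab) == 0))
    return(test_result("pearson_chisq", "codominant",
                       valid = FALSE, reason = "degenerate_table"))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  x2 <- sum((tab - E)^2 / E)
  df <- ncol(tab) - 1
  test_result("pearson_chisq", "codominant", statistic = x2, df = df,
              p_value = stats::pchisq(x2, df, lower.tail = FALSE))
}

#' Cochran-Armitage trend test
#'
#' Score-test (two-sided) for a linear trend in the proportion in group 1
#' across ordered genotype categories with equally spaced scores; normal
#' reference distribution. Algebraically identical to the score test of
#' the additive term in logistic regression of group on genotype, and to
#' `stats::prop.trend.test()`'s chi-square (which equals `Z^2`).
#'
#' @param table 2 x 3 integer matrix with a `scores` attribute (as built
#'   by [build_table()] for the additive model) or default scores 0, 1, 2.
#' @return A `test_result` (statistic is the signed `Z`).
#' @export
cochran_armitage <- function(table) {
  s <- attr(table, "scores")
  if (is.null(s)) s <- seq_len(ncol(table)) - 1
  N <- sum(table)
  R1 <- sum(table[2, ])          # group 1 total
  R0 <- sum(table[1, ])
  Cg <- colSums(table)
  if (R1 == 0 || R0 == 0)
    return(test_result("cochran_armitage", "additive",
                       valid = FALSE, reason = "empty_group"))
  svar <- sum(s^2 * Cg) - sum(s * Cg)^2 / N
  if (svar <= 0)
    return(test_result("cochran_armitage", "additive",
                       valid = FALSE, reason = "zero_score_variance"))
  num <- sum(s * table[2, ]) - R1 * sum(s * Cg) / N
  z <- num / sqrt(R1 * R0 / N^2 * svar)  # score-test variance of the numerator
  test_result("cochran_armitage", "additive", statistic = z, df = NA_real_,
              p_value = 2 * stats::pnorm(-abs(z)))
}

#' Pooled two-proportion z-test (recessive model)
#'
#' Two-sided z-test of equal `aa` proportion between the two groups using
#' the pooled variance estimate and no continuity correction, so that
#' `z^2` equals the Pearson chi-square statistic of the 2 x 2 table.
#'
#' @param table 2 x 2 integer matrix with columns `(AA+Aa, aa)`.
#' @return A `test_result` (statistic is the signed `z`).
#' @export
two_proportion_test <- function(table) {
  n0 <- sum(table[1, ]); n1 <- sum(table[2, ])
  if (n0 == 0 || n1 == 0)
    return(test_result("two_proportion", "recessive",
                       valid = FALSE, reason = "empty_group"))
  pp <- sum(table[, 2]) / (n0 + n1)
  if (pp <= 0 || pp >= 1)
    return(test_result("two_proportion", "recessive",
                       valid = FALSE, reason = "degenerate_pooled_proportion"))
  z <- (table[2, 2] / n1 - table[1, 2] / n0) /
    sqrt(pp * (1 - pp) * (1 / n0 + 1 / n1))
  test_result("two_proportion", "recessive", statistic = z, df = NA_real_,
              p_value = 2 * stats::pnorm(-abs(z)))
}

#' One-way ANOVA of phenotype across genotype categories
#'
#' Equal-variance F-test of equal phenotype means across the non-empty
#' genotype categories (quantitative analysis for the random design,
#' codominant or recessive coding).
#'
#' @param phenotype Numeric vector.
#' @param genotype_category Vector (factor-like) of genotype categories.
#' @return A `test_result` (df is the numerator df).
#' @export
anova_test <- function(phenotype, genotype_category) {
  g <- factor(genotype_category)
  g <- droplevels(g)
  if (nlevels(g) < 2)
    return(test_result("anova", "codominant",
                       valid = FALSE, reason = "single_category"))
  if (length(phenotype) - nlevels(g) < 1)
    return(test_result("anova", "codominant",
                       valid = FALSE, reason = "no_residual_df"))
  ft <- stats::oneway.test(phenotype ~ g, var.equal = TRUE)
  test_result("anova", "codominant",
              statistic = unname(ft$statistic),
              df = unname(ft$parameter[1]),
              p_value = ft$p.value)
}

#' Linear-regression trend test of phenotype on additive genotype
#'
#' Two-sided t-test of the slope in `phenotype ~ genotype` with genotype
#' coded 0/1/2 (quantitative analysis for the random design, additive
#' model).
#'
#' @param phenotype Numeric vector.
#' @param genotype_additive Integer vector of allele counts 0/1/2.
#' @return A `test_result` (statistic is the slope t-value).
#' @export
linear_trend_test <- function(phenotype, genotype_additive) {
  if (stats::var(genotype_additive) == 0)
    return(test_result("linear_regression", "additive",
                       valid = FALSE, reason = "constant_genotype"))
  fit <- stats::lm(phenotype ~ genotype_additive)
  cf <- summary(fit)$coefficients
  test_result("linear_regression", "additive",
              statistic = cf["genotype_additive", "t value"],
              df = fit$df.residual,
              p_value = cf["genotype_additive", "Pr(>|t|)"])
}

#' Likelihood-ratio test from logistic regression of group on genotype
#'
#' Compares the full model (covariates + genotype) against the reduced
#' model (covariates only) by the deviance difference, chi-square
#' distributed under the null. The genotype enters as a factor for the
#' codominant model (2 df when all three classes are observed; empty
#' classes reduce the df) or as the numeric 0/1/2 count for the additive
#' model (1 df). Non-convergence of either fit yields `valid = FALSE`;
#' the IRLS iteration cap is 100 with deviance tolerance 1e-8.
#'
#' @param group Binary 0/1 vector.
#' @param genotype Integer 0/1/2 vector.
#' @param covariates Optional numeric matrix of adjustment covariates
#'   (e.g. principal-component scores), rows matching `group`.
#' @param genetic_model `"codominant"` or `"additive"`.
#' @return A `test_result`.
#' @export
logistic_lrt <- function(group, genotype, covariates = NULL,
                         genetic_model = c("codominant", "additive")) {
  genetic_model <- match.arg(genetic_model)
  if (length(unique(group)) < 2)
    return(test_result("logistic_lrt", genetic_model,
                       valid = FALSE, reason = "single_group"))
  gterm <- if (genetic_model == "codominant")
    droplevels(factor(genotype, levels = 0:2)) else as.numeric(genotype)
  if ((is.factor(gterm) && nlevels(gterm) < 2) ||
      (!is.factor(gterm) && stats::var(gterm) == 0))
    return(test_result("logistic_lrt", genetic_model,
                       valid = FALSE, reason = "constant_genotype"))
  ctrl <- stats::glm.control(epsilon = 1e-8, maxit = 100)
  if (is.null(covariates)) {
    d0 <- data.frame(group = group)
    f0 <- group ~ 1
    f1 <- group ~ g
  } else {
    covariates <- as.matrix(covariates)
    d0 <- data.frame(group = group, covariates)
    f0 <- stats::as.formula(paste("group ~", paste(colnames(d0)[-1],
                                                   collapse = " + ")))
    f1 <- stats::update(f0, . ~ . + g)
  }
  d0$g <- gterm
  fit0 <- suppressWarnings(stats::glm(f0, family = stats::binomial(),
                                      data = d0, control = ctrl))
  fit1 <- suppressWarnings(stats::glm(f1, family = stats::binomial(),
                                      data = d0, control = ctrl))
  if (!fit0$converged || !fit1$converged)
    return(test_result("logistic_lrt", genetic_model,
                       valid = FALSE, reason = "nonconvergence"))
  lrt <- fit0$deviance - fit1$deviance
  df <- fit0$df.residual - fit1$df.residual
  if (df < 1)
    return(test_result("logistic_lrt", genetic_model,
                       valid = FALSE, reason = "no_df"))
  test_result("logistic_lrt", genetic_model, statistic = lrt, df = df,
              p_value = stats::pchisq(lrt, df, lower.tail = FALSE))
}
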