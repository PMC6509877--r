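# Independent small-scale oracles for every test statistic, plus the
# degenerate-input contracts.

test_that("contingency tables tabulate genotype by group per genetic model", {
  s <- toy_sample(genotype = c(0, 1, 2, 2), group = c(1, 1, 0, 0))
  cod <- build_table(s, "codominant")
  expect_equal(unname(cod), rbind(c(0L, 0L, 2L), c(1L, 1L, 0L)))
  rec <- build_table(s, "recessive")
  expect_equal(unname(rec), rbind(c(0L, 2L), c(2L, 0L)))
  add <- build_table(s, "additive")
  expect_equal(attr(add, "scores"), 0:2)
  # empty genotype category allowed
  s2 <- toy_sample(genotype = c(0, 0, 1, 1), group = c(0, 0, 1, 1))
  expect_equal(unname(colSums(build_table(s2, "codominant"))), c(2L, 2L, 0L))
  expect_error(build_table(toy_sample(0:1, c(NA, 1))), "group")
})

test_that("Pearson chi-square matches closed-form arithmetic", {
  r <- pearson_chisq(matrix(c(10, 20, 20, 10), 2))
  expect_equal(r$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(r$p_value, pchisq(20 / 3, 1, lower.tail = FALSE))
  # proportional rows carry no signal
  r0 <- pearson_chisq(rbind(c(10, 20, 30), c(20, 40, 60)))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # empty column reduces df
  r1 <- pearson_chisq(rbind(c(10, 20, 0), c(20, 10, 0)))
  expect_equal(r1$df, 1)
  # fewer than two non-empty columns is degenerate
  expect_false(pearson_chisq(rbind(c(10, 0, 0), c(20, 0, 0)))$valid)
})

test_that("trend test agrees with stats::prop.trend.test and logistic score", {
  set.seed(5)
  for (i in 1:20) {
    tab <- matrix(rpois(6, 15) + 1L, 2)
    attr(tab, "scores") <- 0:2
    ca <- cochran_armitage(tab)
    ptt <- prop.trend.test(tab[2, ], colSums(tab), score = 0:2)
    expect_equal(ca$statistic^2, unname(ptt$statistic), tolerance = 1e-10)
    # score test from additive logistic regression on the expanded data
    g <- rep(rep(0:2, 2), as.vector(t(tab)))
    y <- rep(rep(0:1, each = 3), as.vector(t(tab)))
    sc <- anova(glm(y ~ 1, family = binomial), glm(y ~ g, family = binomial),
                test = "Rao")
    expect_equal(ca$statistic^2, sc$Rao[2], tolerance = 1e-4)
    # two-sided: invariant to swapping the group rows
    expect_equal(cochran_armitage(tab[2:1, ])$p_value, ca$p_value,
                 tolerance = 1e-12)
  }
})

test_that("trend test is calibrated against an exhaustive permutation null", {
  # small table: exact conditional p-value by enumeration of all 2x3
  # tables with the observed margins, ordered by |Z|
  tab <- rbind(c(15, 12, 9), c(6, 12, 18))
  attr(tab, "scores") <- 0:2
  obs <- cochran_armitage(tab)
  C <- colSums(tab); R1 <- sum(tab[2, ])
  p_exact <- 0
  for (a in 0:min(C[1], R1)) for (b in 0:min(C[2], R1 - a)) {
    d <- R1 - a - b
    if (d < 0 || d > C[3]) next
    t2 <- rbind(C - c(a, b, d), c(a, b, d))
    attr(t2, "scores") <- 0:2
    pr <- exp(lchoose(C[1], a) + lchoose(C[2], b) + lchoose(C[3], d) -
                lchoose(sum(C), R1))
    z2 <- cochran_armitage(t2)
    if (z2$valid && abs(z2$statistic) >= abs(obs$statistic) - 1e-12)
      p_exact <- p_exact + pr
  }
  expect_lt(abs(obs$p_value - p_exact), 0.02)
  # degenerate: all mass in one genotype column
  degen <- rbind(c(0, 5, 0), c(0, 7, 0))
  attr(degen, "scores") <- 0:2
  expect_false(cochran_armitage(degen)$valid)
  # identical rows give Z = 0, p = 1
  eq <- rbind(c(10, 10, 10), c(10, 10, 10))
  attr(eq, "scores") <- 0:2
  expect_equal(cochran_armitage(eq)$statistic, 0)
  expect_equal(cochran_armitage(eq)$p_value, 1)
})

test_that("pooled two-proportion z matches hand arithmetic and chi-square", {
  tab <- rbind(c(470, 30), c(480, 20))
  r <- two_proportion_test(tab)
  expect_equal(abs(r$statistic), 0.02 / sqrt(0.05 * 0.95 * 2 / 500),
               tolerance = 1e-12)
  set.seed(6)
  for (i in 1:15) {
    t2 <- matrix(rpois(4, 25) + 1L, 2)
    z <- two_proportion_test(t2)
    x2 <- pearson_chisq(t2)
    expect_equal(z$statistic^2, x2$statistic, tolerance = 1e-10)
    expect_equal(z$p_value, x2$p_value, tolerance = 1e-10)
  }
  expect_equal(two_proportion_test(rbind(c(30, 10), c(60, 20)))$statistic, 0)
  expect_false(two_proportion_test(rbind(c(40, 0), c(40, 0)))$valid)
})

test_that("ANOVA matches a from-scratch sums-of-squares computation", {
  y <- c(1.1, 0.9, 1.3, 2.2, 2.0, 2.4, 3.3, 2.9, 3.1)
  g <- rep(c("AA", "Aa", "aa"), each = 3)
  r <- anova_test(y, g)
  grand <- mean(y)
  ssb <- sum(3 * (tapply(y, g, mean) - grand)^2)
  ssw <- sum((y - ave(y, g))^2)
  f_oracle <- (ssb / 2) / (ssw / 6)
  expect_equal(r$statistic, f_oracle, tolerance = 1e-10)
  expect_equal(r$df, 2)
  # two groups: F = t^2 from the pooled t-test
  y2 <- rnorm(30); g2 <- rep(0:1, 15)
  tt <- t.test(y2 ~ g2, var.equal = TRUE)
  expect_equal(anova_test(y2, g2)$statistic, unname(tt$statistic)^2,
               tolerance = 1e-10)
  expect_false(anova_test(y2, rep(1, 30))$valid)
})

test_that("linear trend test matches the normal-equations oracle", {
  g <- c(0, 0, 1, 1, 2, 2)
  y <- c(0.3, -0.1, 0.8, 1.1, 2.2, 1.7)
  r <- linear_trend_test(y, g)
  # closed-form slope, residual variance and t
  b <- sum((g - mean(g)) * (y - mean(y))) / sum((g - mean(g))^2)
  a <- mean(y) - b * mean(g)
  s2 <- sum((y - a - b * g)^2) / 4
  t_oracle <- b / sqrt(s2 / sum((g - mean(g))^2))
  expect_equal(r$statistic, t_oracle, tolerance = 1e-10)
  expect_equal(r$p_value, 2 * pt(-abs(t_oracle), 4), tolerance = 1e-10)
  # perfectly linear data
  rp <- linear_trend_test(2 * g + rnorm(6, sd = 1e-8), g)
  expect_lt(rp$p_value, 1e-10)
  expect_false(linear_trend_test(y, rep(1, 6))$valid)
})

test_that("logistic LRT matches an independent IRLS fit", {
  # tiny dataset with one covariate, fit by hand-rolled Newton iterations
  y <- c(0, 1, 1, 0, 1, 0, 0, 1)
  g <- c(0, 1, 2, 0, 1, 2, 1, 2)
  x <- c(-0.5, 0.2, 0.3, -1.1, 0.8, 1.2, -0.3, 0.1)
  irls_dev <- function(X, y) {
    beta <- rep(0, ncol(X))
    for (it in 1:60) {
      eta <- drop(X %*% beta); mu <- plogis(eta)
      W <- mu * (1 - mu)
      beta <- beta + solve(crossprod(X, X * W), crossprod(X, y - mu))
    }
    mu <- plogis(drop(X %*% beta))
    -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
  }
  d0 <- irls_dev(cbind(1, x), y)
  d1 <- irls_dev(cbind(1, x, g), y)
  r <- logistic_lrt(y, g, covariates = cbind(pc = x), "additive")
  expect_equal(r$statistic, d0 - d1, tolerance = 1e-8)
  expect_equal(r$df, 1)
  expect_equal(r$p_value, pchisq(d0 - d1, 1, lower.tail = FALSE),
               tolerance = 1e-8)
})

test_that("logistic LRT df follows the genotype coding and flags degeneracy", {
  set.seed(8)
  g <- sample(0:2, 200, replace = TRUE)
  y <- rbinom(200, 1, 0.5)
  expect_equal(logistic_lrt(y, g, NULL, "codominant")$df, 2)
  expect_equal(logistic_lrt(y, g, NULL, "additive")$df, 1)
  # an absent genotype class reduces the codominant df
  g2 <- sample(0:1, 200, replace = TRUE)
  expect_equal(logistic_lrt(y, g2, NULL, "codominant")$df, 1)
  expect_false(logistic_lrt(y, rep(1L, 200), NULL, "additive")$valid)
  expect_false(logistic_lrt(rep(1, 200), g, NULL, "additive")$valid)
})
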