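test_that("Balding-Nichols frequencies have the stated beta moments", {
  # pin the generating frequency at 0.5 so the moment identities are exact
  bn <- bn_params(n_snps = 10000, fst = 0.01,
                  ancestral_freq_range = c(0.5, 0.5))
  pan <- balding_nichols_freqs(bn, n_pops = 2, seed = 1)
  f <- as.vector(pan$freqs)
  expect_equal(mean(f), 0.5, tolerance = 0.005)
  expect_lt(abs(var(f) - 0.5 * 0.5 * 0.01), 1e-4)
  expect_error(bn_params(fst = 0), "fst")
  expect_error(bn_params(fst = 1), "fst")
})

test_that("generating frequencies stay inside the requested range", {
  bn <- bn_params(n_snps = 500, fst = 0.2, ancestral_freq_range = c(0.3, 0.4))
  pan <- balding_nichols_freqs(bn, n_pops = 3, seed = 2)
  expect_true(all(pan$ancestral_freq >= 0.3 & pan$ancestral_freq <= 0.4))
  expect_equal(dim(pan$freqs), c(500L, 3L))
  expect_true(all(pan$freqs >= 0 & pan$freqs <= 1))
})

test_that("synthetic European panel satisfies its frequency filters", {
  pan <- synthetic_european_panel(1000, seed = 3)
  expect_equal(pan$pop_labels, c("TSI", "IBS", "GBR", "FIN"))
  expect_equal(unname(pan$phenotype_means), c(0.3, 0.2, 0, -0.1))
  expect_equal(unname(pan$candidate_mafs), c(0.01, 0.02, 0.05, 0.1))
  f <- pan$freqs
  expect_equal(nrow(f), 1000L)
  overall_maf <- pmin(rowMeans(f), 1 - rowMeans(f))
  expect_true(all(overall_maf > 0.05))
  expect_true(all(apply(f, 1, max) >= 0.1))
  expect_true(all(f > 0 & f < 1))
})

test_that("frequency panels round-trip through tab-delimited text", {
  pan <- synthetic_european_panel(50, seed = 4)
  path <- tempfile(fileext = ".tsv")
  write_frequency_panel(pan, path)
  back <- read_frequency_panel(path)
  expect_equal(back$pop_labels, pan$pop_labels)
  expect_equal(unname(back$freqs), unname(pan$freqs), tolerance = 1e-12)
})

test_that("panel genotypes follow within-population HWE frequencies", {
  pan <- structure(list(pop_labels = c("a", "b"),
                        freqs = cbind(a = c(0, 1, 0.3), b = c(0.5, 0.5, 0.8))),
                   class = "frequency_panel")
  G <- simulate_panel_genotypes(pan, rep("a", 50), seed = 5)
  expect_true(all(G[, 1] == 0L))   # frequency 0 -> all reference
  expect_true(all(G[, 2] == 2L))   # frequency 1 -> all alternate
  big <- simulate_panel_genotypes(pan, rep(c("a", "b"), each = 2500), seed = 6)
  emp_a <- mean(big[1:2500, 3]) / 2
  emp_b <- mean(big[2501:5000, 3]) / 2
  expect_lt(abs(emp_a - 0.3), 4 * sqrt(0.3 * 0.7 / 5000))
  expect_lt(abs(emp_b - 0.8), 4 * sqrt(0.8 * 0.2 / 5000))
  expect_error(simulate_panel_genotypes(pan, c("a", "zzz")), "unknown")
})

test_that("standardization implements the pseudo-count frequency estimate", {
  G <- rbind(c(0L, 0L), c(2L, 0L))
  st <- standardize_genotypes(G)
  expect_equal(st$est_freq[1], 0.5)         # (1 + 2) / (2 + 4)
  expect_equal(st$standardized[, 1], c(-2, 2))
  expect_equal(st$est_freq[2], 1 / 6)       # all-zero column: 1 / (2 + 2n)
  set.seed(7)
  G2 <- matrix(rbinom(200 * 30, 2, 0.4), 200, 30)
  st2 <- standardize_genotypes(G2)
  expect_true(all(abs(colMeans(st2$standardized)) < 1e-10))
  expect_true(all(is.finite(st2$standardized)))
})

test_that("principal components are orthogonal with nonincreasing variance", {
  set.seed(8)
  X <- standardize_genotypes(matrix(rbinom(150 * 400, 2, 0.3),
                                    150, 400))$standardized
  S <- compute_pcs(X, k = 5)
  crossmat <- crossprod(S)
  expect_true(all(abs(crossmat[upper.tri(crossmat)]) < 1e-6))
  v <- apply(S, 2, var)
  expect_true(all(diff(v) <= 1e-8))
  # rank-1 geometry: PC1 carries everything
  u <- rnorm(60); w <- rnorm(100)
  X1 <- outer(u, w)
  S1 <- compute_pcs(sweep(X1, 2, colMeans(X1)), k = 3)
  expect_gt(abs(cor(S1[, 1], u - mean(u))), 1 - 1e-8)
  expect_lt(var(S1[, 2]) / var(S1[, 1]), 1e-10)
  expect_error(compute_pcs(X, k = 200), "exceeds")
})

test_that("randomized and exact SVD branches agree on the leading PCs", {
  set.seed(9)
  pan <- balding_nichols_freqs(bn_params(n_snps = 800, fst = 0.1), 2, seed = 10)
  G <- simulate_panel_genotypes(pan, rep(1:2, each = 200), seed = 11)
  X <- standardize_genotypes(G)$standardized
  Se <- compute_pcs(X, k = 3, exact = TRUE)
  Sr <- compute_pcs(X, k = 3, exact = FALSE)
  # sign is arbitrary; higher noise PCs have near-tied singular values and
  # may rotate among themselves, so compare the structured PC1 and scales
  expect_gt(abs(cor(Se[, 1], Sr[, 1])), 0.999)
  expect_lt(max(abs(apply(Sr, 2, sd) / apply(Se, 2, sd) - 1)), 0.05)
})

test_that("PC scores are equivariant under permuting individuals", {
  pan <- balding_nichols_freqs(bn_params(n_snps = 600, fst = 0.05), 2, seed = 12)
  G <- simulate_panel_genotypes(pan, rep(1:2, each = 150), seed = 13)
  X <- standardize_genotypes(G)$standardized
  set.seed(14); S <- compute_pcs(X, k = 3)
  perm <- sample(nrow(X))
  set.seed(14); Sp <- compute_pcs(X[perm, ], k = 3)
  for (j in 1:3)
    expect_equal(abs(cor(S[perm, j], Sp[, j])), 1, tolerance = 1e-6)
})

test_that("PC1 separates two Balding-Nichols populations at default Fst", {
  # default differentiation (Fst = 0.01), genome-scale SNP count
  set.seed(15)
  n_sep <- 0
  reps <- 8
  for (r in 1:reps) {
    pan <- balding_nichols_freqs(bn_params(n_snps = 5000, fst = 0.01), 2)
    G <- simulate_panel_genotypes(pan, rep(1:2, each = 500))
    S <- compute_pcs(standardize_genotypes(G)$standardized, k = 5)
    pv <- wilcox.test(S[1:500, 1], S[501:1000, 1])$p.value
    if (pv < 1e-10) n_sep <- n_sep + 1
  }
  expect_gte(n_sep, reps - 1)
})

test_that("Fisher screening selects only strongly differentiated SNPs", {
  # one engineered high-contrast SNP among near-identical ones
  set.seed(16)
  freqs <- cbind(runif(30, 0.4, 0.41), runif(30, 0.4, 0.41))
  freqs[7, ] <- c(0.1, 0.9)
  pan <- structure(list(pop_labels = c("p1", "p2"), freqs = freqs),
                   class = "frequency_panel")
  G <- simulate_panel_genotypes(pan, rep(c("p1", "p2"), each = 500))
  expect_equal(select_confounded_candidate(G, rep(1:2, each = 500)), 7L)
  # near-identical frequencies select nothing at the default threshold
  pan0 <- structure(list(pop_labels = c("p1", "p2"),
                         freqs = cbind(rep(0.5, 20), rep(0.503, 20))),
                    class = "frequency_panel")
  for (r in 1:5) {
    G0 <- simulate_panel_genotypes(pan0, rep(c("p1", "p2"), each = 500))
    expect_error(select_confounded_candidate(G0, rep(1:2, each = 500)),
                 class = "epsstrat_no_candidate")
  }
  # threshold 0 admits any polymorphic SNP
  expect_true(select_confounded_candidate(G, rep(1:2, each = 500),
                                          threshold = 0) %in% 1:30)
  expect_error(select_confounded_candidate(G, rep(1, 1000)), "two populations")
})
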