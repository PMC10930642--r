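test_that("kinship matches the VanRaden formula on hand-checkable cases", {
  # duplicated samples: off-diagonal equals both diagonals
  set.seed(61)
  d <- toy_dataset(6, 200, p = runif(200, 0.2, 0.5))
  d$geno[2, ] <- d$geno[1, ]
  K <- compute_kinship(d$geno)
  expect_equal(K[1, 2], K[1, 1])
  expect_equal(K[1, 2], K[2, 2])
  # opposite homozygotes at every marker with p = 0.5: Z rows are -1/+1,
  # so G = ZZ'/(2*sum(p*q)) = -m / (m/2) = -2 off the diagonal
  g2 <- rbind(rep(0L, 50), rep(2L, 50))
  rownames(g2) <- c("x", "y")
  K2 <- compute_kinship(g2)
  expect_equal(K2["x", "y"], -2)
  # independent genotypes: off-diagonals shrink toward 0
  d3 <- toy_dataset(50, 5000, p = runif(5000, 0.1, 0.5))
  K3 <- compute_kinship(d3$geno)
  expect_lt(max(abs(K3[upper.tri(K3)])), 0.1)
  expect_error(compute_kinship(matrix(0L, 3, 4)), "polymorphic")
})

test_that("principal components separate subpopulations and are deterministic", {
  set.seed(62)
  n <- 60; m <- 400
  p1 <- runif(m, 0.1, 0.9)
  p2 <- pmin(0.95, pmax(0.05, p1 + rnorm(m, 0, 0.25)))
  g <- rbind(sapply(p1, function(p) rbinom(n / 2, 2, p)),
             sapply(p2, function(p) rbinom(n / 2, 2, p)))
  rownames(g) <- paste0("s", 1:n)
  pcs <- compute_pcs(g, 3)
  grp <- rep(c(1, 2), each = n / 2)
  # PC1 separates the groups: between-group distance dominates
  expect_gt(abs(mean(pcs[grp == 1, 1]) - mean(pcs[grp == 2, 1])),
            2 * mean(tapply(pcs[, 1], grp, sd)))
  # duplicated samples score identically; sign fixed by loading convention
  g[2, ] <- g[1, ]
  pcs2 <- compute_pcs(g, 2)
  expect_equal(pcs2[1, ], pcs2[2, ])
  pcs3 <- compute_pcs(g, 2)
  expect_identical(pcs2, pcs3)
  expect_error(compute_pcs(g, 60), "smaller")
  # k = 0 gives an empty covariate block that scans still accept
  p0 <- compute_pcs(g, 0)
  expect_equal(dim(p0), c(n, 0L))
})

test_that("GLM scan matches closed-form OLS and flags degenerate markers", {
  g <- matrix(c(0L, 0L, 1L, 1L, 2L, 2L,
                1L, 1L, 1L, 1L, 1L, 1L), ncol = 2,
              dimnames = list(paste0("s", 1:6), c("mA", "mB")))
  map <- marker_map(c("mA", "mB"), c("1", "1"), c(100L, 200L))
  y <- c(1, 1, 2, 2, 3, 3)
  sc <- glm_scan(g, map, y)
  expect_equal(sc$result$beta[1], 1.0)
  expect_equal(sc$result$p_value[1], .Machine$double.xmin)  # exact fit
  # constant dosage marker: untestable
  expect_true(sc$result$untestable[2])
  expect_equal(sc$result$beta[2], 0)
  expect_equal(sc$result$p_value[2], 1)
  # collinear covariates are named
  cv <- cbind(a = y, b = 2 * y)
  expect_error(glm_scan(g, map, y, cv), "collinear")
})

test_that("GLM type-I error is nominal on independent null markers", {
  set.seed(63)
  n <- 200; m <- 10000
  d <- toy_dataset(n, m, p = runif(m, 0.1, 0.5))
  y <- rnorm(n)
  sc <- glm_scan(d$geno, d$map, y)
  frac <- mean(sc$result$p_value < 0.05)
  tol <- 3 * sqrt(0.05 * 0.95 / m)
  expect_lt(abs(frac - 0.05), tol)
  expect_gt(sc$lambda_gc, 0.9)
  expect_lt(sc$lambda_gc, 1.1)
})

test_that("REML variance components match a direct grid-search oracle", {
  set.seed(64)
  n <- 20
  d <- toy_dataset(n, 500, p = runif(500, 0.1, 0.5))
  d$geno[1:10, ] <- d$geno[rep(1:2, 5), ]  # relatedness so sigma_g2 > 0
  K <- compute_kinship(d$geno)
  X <- cbind(rep(1, n))
  u <- t(chol(0.5 * (K + diag(1e-6, n)))) %*% rnorm(n)
  y <- as.vector(2 + u + rnorm(n, sd = sqrt(0.3)))
  ms <- mlm_scan(d$geno[, 1:5], d$map[1:5, ], y, K)
  oracle <- reml_grid_oracle(y, X, K)
  expect_equal(ms$vc$sigma_g2, unname(oracle["sg2"]), tolerance = 1e-3)
  expect_equal(ms$vc$sigma_e2, unname(oracle["se2"]), tolerance = 1e-3)
})

test_that("MLM collapses to GLM when the polygenic variance is zero", {
  set.seed(66)
  n <- 80
  d <- toy_dataset(n, 300, p = runif(300, 0.1, 0.5))
  K <- compute_kinship(d$geno)
  y <- rnorm(n)  # h2 = 0
  gl <- glm_scan(d$geno, d$map, y)
  ml <- mlm_scan(d$geno, d$map, y, K)
  expect_equal(ml$vc$sigma_g2, 0)
  expect_equal(ml$scan$result$p_value, gl$result$p_value,
               tolerance = 1e-6)
  expect_equal(ml$scan$result$beta, gl$result$beta, tolerance = 1e-6)
})

test_that("exact per-marker REML agrees with P3D on a small scan", {
  set.seed(66)
  n <- 40
  d <- toy_dataset(n, 20, p = runif(20, 0.2, 0.5))
  d$geno[1:20, ] <- d$geno[rep(1:4, 5), ]
  K <- compute_kinship(d$geno)
  u <- t(chol(K + diag(1e-6, n))) %*% rnorm(n)
  y <- as.vector(1 + 0.7 * u + rnorm(n))
  p3d <- mlm_scan(d$geno, d$map, y, K)
  exact <- mlm_scan(d$geno, d$map, y, K, exact_reml = TRUE)
  expect_gt(cor(-log10(p3d$scan$result$p_value),
                -log10(exact$scan$result$p_value)), 0.9)
})

test_that("Bonferroni thresholds and lambda follow their definitions", {
  expect_equal(bonferroni_threshold(29503), 3.3895e-7, tolerance = 1e-4)
  expect_equal(bonferroni_threshold(1), 0.01)
  expect_equal(bonferroni_threshold(10, 0.05), 0.005)
  expect_error(bonferroni_threshold(0), "m_tested")
  expect_equal(lambda_gc(rep(0.5, 11)), 1.0)
  set.seed(67)
  expect_equal(lambda_gc(runif(20000)), 1.0, tolerance = 0.05)
  p <- runif(5000)
  expect_gt(lambda_gc(p / 2), lambda_gc(p))
  expect_error(lambda_gc(NA_real_), "p-values")
})

test_that("genotype-stratified summaries use allele labels and undefined group", {
  dosage <- c(2L, 2L, 1L, 1L, 0L, NA)
  y <- c(3.2, 3.3, 3.2, 3.1, 3.0, 3.32)
  s <- genotype_trait_summary(dosage, c("T", "C"), y)
  expect_equal(s$genotype, c("TT", "CT", "CC", "undefined"))
  expect_equal(s$n, c(1L, 2L, 2L, 1L))
  expect_equal(s[s$genotype == "CC", "mean"], 3.25)
  expect_equal(s[s$genotype == "CC", "sd"], sd(c(3.2, 3.3)))
  expect_true(is.na(s[s$genotype == "undefined", "sd"]))
  yc <- rep(5, 6)
  sc <- genotype_trait_summary(dosage, c("T", "C"), yc)
  expect_true(all(sc$mean == 5))
  expect_true(all(sc$sd[sc$n > 1] == 0))
})

test_that("a planted QTL is recovered with monotone genotype means", {
  cfg <- sim_config(n_samples = 150, n_chrom = 3, markers_per_chrom = 600,
                    generations = 4, n_founder_haplotypes = 300,
                    inbred_mating_fraction = 0, seed = 68)
  sim <- simulate_dataset(cfg, qtl = list(marker = 900, share = 0.2,
                                          h2_polygenic = 0.5,
                                          sigma_e2 = 0.01))
  K <- compute_kinship(sim$geno)
  pcs <- compute_pcs(sim$geno, 3)
  ms <- mlm_scan(sim$geno, sim$map, sim$pheno, K, pcs)
  res <- ms$scan$result
  expect_equal(which.min(res$p_value), 900L)
  beta_hat <- res$beta[900]
  gts <- genotype_trait_summary(sim$geno[, 900], c("A", "B"), sim$pheno)
  mns <- gts$mean[match(c("AA", "BA", "BB"), gts$genotype)]
  if (beta_hat > 0) expect_true(all(diff(mns) > 0))
  else expect_true(all(diff(mns) < 0))
})
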