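test_that("founder pool is deterministic, bounded, and LD-controllable", {
  cfg <- sim_config(n_samples = 10, n_chrom = 2, markers_per_chrom = 400,
                    seed = 71)
  p1 <- simulate_founder_haplotypes(cfg)
  p2 <- simulate_founder_haplotypes(cfg)
  expect_identical(p1, p2)
  for (ch in names(p1)) {
    expect_true(all(p1[[ch]]$freq >= 0.05 & p1[[ch]]$freq <= 0.95))
    expect_false(is.unsorted(p1[[ch]]$pos, strictly = TRUE))
  }
  # ld_rho = 0: adjacent-haplotype-allele r2 ~ 0
  cfg0 <- sim_config(n_samples = 10, n_chrom = 1, markers_per_chrom = 2000,
                     n_founder_haplotypes = 100, ld_rho = 0, seed = 72)
  H <- simulate_founder_haplotypes(cfg0)[["1"]]$H
  r <- sapply(seq_len(ncol(H) - 1), function(j)
    suppressWarnings(cor(H[, j], H[, j + 1])))
  expect_lt(mean(r^2, na.rm = TRUE), 0.02)
  # ld_rho > 0 raises adjacent correlation
  cfg5 <- sim_config(n_samples = 10, n_chrom = 1, markers_per_chrom = 2000,
                     n_founder_haplotypes = 100, ld_rho = 0.5, seed = 72)
  H5 <- simulate_founder_haplotypes(cfg5)[["1"]]$H
  r5 <- sapply(seq_len(ncol(H5) - 1), function(j)
    suppressWarnings(cor(H5[, j], H5[, j + 1])))
  expect_gt(mean(r5^2, na.rm = TRUE), mean(r^2, na.rm = TRUE) + 0.1)
})

test_that("identical config and seed give bit-identical datasets", {
  cfg <- sim_config(n_samples = 15, n_chrom = 2, markers_per_chrom = 300,
                    seed = 73)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$geno, s2$geno)
  expect_identical(s1$truth$autozygous, s2$truth$autozygous)
})

test_that("unrelated founders with no pedigree depth carry no autozygosity", {
  cfg <- sim_config(n_samples = 30, n_chrom = 2, markers_per_chrom = 300,
                    generations = 0, n_founder_haplotypes = 60, seed = 74)
  sim <- simulate_dataset(cfg)
  expect_true(all(sim$truth$autozygosity < 1e-12))
})

test_that("full-sib matings produce autozygosity near pedigree expectation", {
  # one round of full-sib mating after a random generation: F ~ 0.25
  fr <- sapply(c(75, 76, 77), function(seed) {
    cfg <- sim_config(n_samples = 60, n_chrom = 3, markers_per_chrom = 300,
                      generations = 2, inbred_mating_fraction = 1,
                      n_founder_haplotypes = 80, seed = seed)
    mean(simulate_dataset(cfg)$truth$autozygosity)
  })
  expect_true(all(fr > 0.15 & fr < 0.35))
})

test_that("markers inside truth intervals are homozygous without genotype error", {
  cfg <- sim_config(n_samples = 25, missing_rate = 0, het_error_rate = 0,
                    seed = 78)
  sim <- simulate_dataset(cfg)
  tr <- sim$truth$autozygous
  bad <- 0L; tot <- 0L
  for (i in seq_len(nrow(tr))) {
    cols <- which(sim$map$chrom == tr$chrom[i] &
                    sim$map$pos_bp >= tr$start_bp[i] &
                    sim$map$pos_bp <= tr$end_bp[i])
    g <- sim$geno[tr$sample_id[i], cols]
    tot <- tot + length(g)
    bad <- bad + sum(g == 1L, na.rm = TRUE)
  }
  expect_gt(tot, 1000)
  expect_gte(1 - bad / tot, 0.99)
})

test_that("default configuration populates all five ROH length classes", {
  cfg <- sim_config(n_samples = 80, seed = 79)
  sim <- simulate_dataset(cfg)
  ds <- build_dataset(sim$geno, sim$map, qc_config(profile = "roh"))
  segs <- call_roh_all(ds$geno, ds$map)
  expect_setequal(unique(segs$length_class),
                  c("1-2", "2-4", "4-8", "8-16", ">16"))
})

test_that("planted sweeps update truth and guarantee carrier homozygosity", {
  cfg <- sim_config(n_samples = 40, n_founder_haplotypes = 200,
                    inbred_mating_fraction = 0, missing_rate = 0,
                    het_error_rate = 0, seed = 80)
  sim <- simulate_dataset(cfg,
                          sweeps = data.frame(chrom = "1", start_bp = 5e6,
                                              end_bp = 9e6,
                                              carrier_fraction = 1))
  expect_equal(nrow(sim$truth$sweeps), 1L)
  cols <- sim$map$chrom == "1" & sim$map$pos_bp >= 5e6 & sim$map$pos_bp <= 9e6
  expect_true(all(sim$geno[, cols] != 1L))
  # truth autozygosity includes the swept region for everyone
  expect_true(all(sim$truth$autozygosity >= (4e6 - 1) / sim$truth$autosome_bp))
  # sub-minimum regions warn
  expect_warning(plant_sweep(sim, "2", 1e6, 1.5e6, 0.5), "shorter")
})

test_that("phenotype simulation honors seed, scale, and variance shares", {
  cfg <- sim_config(n_samples = 60, n_chrom = 2, markers_per_chrom = 400,
                    seed = 81)
  sim <- simulate_dataset(cfg)
  K <- compute_kinship(sim$geno)
  p1 <- simulate_phenotype(sim$geno, K, qtl_marker = 100, beta = 0.1,
                           h2_polygenic = 0.4, sigma_e2 = 0.01, seed = 5)
  p2 <- simulate_phenotype(sim$geno, K, qtl_marker = 100, beta = 0.1,
                           h2_polygenic = 0.4, sigma_e2 = 0.01, seed = 5)
  expect_identical(p1$y, p2$y)
  expect_equal(p1$components$sigma_g2, 0.4 / 0.6 * 0.01)
  # beta = 0, h2 = 0: pure noise at the residual scale
  p0 <- simulate_phenotype(sim$geno, K, qtl_marker = NULL, beta = 0,
                           h2_polygenic = 0, sigma_e2 = 1, seed = 6)
  expect_equal(var(p0$y), 1, tolerance = 0.4)
  expect_error(simulate_phenotype(sim$geno, K, NULL, 0, 0, -1, seed = 1),
               "sigma_e2")
  # qtl_beta_for_share hits its variance target
  d <- sim$geno[, 100]
  b <- qtl_beta_for_share(d, 0.25, 4)
  expect_equal(var(d * b), 1, tolerance = 1e-9)
})
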