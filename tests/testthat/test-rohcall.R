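hom_run <- function(n) rep(0L, n)  # homozygous reference calls

test_that("single-sample caller applies all four rules at their boundaries", {
  p <- roh_params()
  # 30 homozygous markers spanning 1,000,000..2,500,000
  pos <- as.integer(round(seq(1e6, 2.5e6, length.out = 30)))
  seg <- call_roh_sample(hom_run(30), pos, p)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$n_hom, 30L)
  expect_equal(seg$length_bp, 1500001)
  # 24 homozygous markers spanning 2 Mbp: fails min_snp
  pos24 <- as.integer(round(seq(1e6, 3e6, length.out = 24)))
  expect_equal(nrow(call_roh_sample(hom_run(24), pos24, p)), 0L)
  # 30 homozygous markers spanning 900 kbp: fails min length
  pos9 <- as.integer(round(seq(1e6, 1.9e6 - 1, length.out = 30)))
  expect_equal(nrow(call_roh_sample(hom_run(30), pos9, p)), 0L)
  # heterozygote splits; halves each < 1 Mbp -> nothing
  d <- hom_run(41); d[21] <- 1L
  posh <- as.integer(round(seq(1e6, 2.9e6, length.out = 41)))
  expect_equal(nrow(call_roh_sample(d, posh, p)), 0L)
  # five interspersed missing within a 1.2 Mbp run are tolerated
  d5 <- hom_run(30)
  d5 <- append(d5, rep(NA_integer_, 5), after = 15)
  pos5 <- as.integer(round(seq(1e6, 2.2e6, length.out = 35)))
  seg5 <- call_roh_sample(d5, pos5, p)
  expect_equal(nrow(seg5), 1L)
  expect_equal(seg5$n_missing, 5L)
  # a sixth missing splits the run
  d6 <- hom_run(60)
  d6 <- append(d6, rep(NA_integer_, 6), after = 30)
  pos6 <- as.integer(round(seq(1e6, 4.3e6, length.out = 66)))
  seg6 <- call_roh_sample(d6, pos6, p)
  expect_equal(nrow(seg6), 2L)
  expect_true(all(seg6$n_missing <= 5))
  expect_error(call_roh_sample(hom_run(3), c(5L, 2L, 9L), p), "increasing")
})

test_that("caller matches the brute-force subinterval oracle on random data", {
  set.seed(424)
  for (rep_ in 1:120) {
    ch <- random_chromosome(sample(20:200, 1),
                            p_het = runif(1, 0.02, 0.3),
                            p_miss = runif(1, 0, 0.15))
    p <- random_roh_params()
    fast <- call_roh_sample(ch$dosage, ch$pos, p)
    slow <- oracle_roh(ch$dosage, ch$pos, p)
    expect_equal(fast$start_bp, slow$start_bp)
    expect_equal(fast$end_bp, slow$end_bp)
    expect_equal(fast$n_hom, slow$n_hom)
    expect_equal(fast$n_missing, slow$n_missing)
  }
})

test_that("segments are maximal, non-overlapping, and monotone in thresholds", {
  set.seed(99)
  for (rep_ in 1:25) {
    ch <- random_chromosome(150, p_het = 0.05, p_miss = 0.1)
    p <- roh_params(min_snp = 10, min_length_bp = 3e5)
    seg <- call_roh_sample(ch$dosage, ch$pos, p)
    if (nrow(seg) > 1) {
      expect_true(all(seg$start_bp[-1] > seg$end_bp[-nrow(seg)]))
    }
    stricter_snp <- call_roh_sample(ch$dosage, ch$pos,
                                    roh_params(min_snp = 15,
                                               min_length_bp = 3e5))
    stricter_len <- call_roh_sample(ch$dosage, ch$pos,
                                    roh_params(min_snp = 10,
                                               min_length_bp = 6e5))
    expect_lte(nrow(stricter_snp), nrow(seg))
    expect_lte(nrow(stricter_len), nrow(seg))
  }
})

test_that("genome-wide calling recovers planted tracts and orders output", {
  set.seed(11)
  cfg <- sim_config(n_samples = 20, n_chrom = 2, markers_per_chrom = 600,
                    missing_rate = 0, het_error_rate = 0, seed = 5)
  sim <- simulate_dataset(cfg)
  segs <- call_roh_all(sim$geno, sim$map)
  expect_true(all(segs$n_hom >= 25))
  expect_true(all(segs$length_bp >= 1e6))
  # deterministic (sample, chrom, start) order
  o <- order(match(segs$sample_id, rownames(sim$geno)),
             as.numeric(segs$chrom), segs$start_bp)
  expect_equal(o, seq_len(nrow(segs)))
  # all-heterozygous matrix yields nothing
  het <- matrix(1L, 3, 600, dimnames = list(letters[1:3], NULL))
  m2 <- sim$map[sim$map$chrom == "1", ]
  colnames(het) <- m2$marker_id
  expect_equal(nrow(call_roh_all(het, m2)), 0L)
  # fully homozygous chromosome gives exactly one segment per sample
  hom <- matrix(0L, 3, 600, dimnames = list(letters[1:3], m2$marker_id))
  segs2 <- call_roh_all(hom, m2)
  expect_equal(nrow(segs2), 3L)
  # X markers are refused
  mx <- m2; mx$chrom <- "X"
  expect_error(call_roh_all(hom, mx), "autosomes")
})

test_that("permuting sample order only permutes output rows", {
  set.seed(12)
  cfg <- sim_config(n_samples = 12, n_chrom = 2, markers_per_chrom = 500,
                    seed = 9)
  sim <- simulate_dataset(cfg)
  seg1 <- call_roh_all(sim$geno, sim$map)
  perm <- sample(nrow(sim$geno))
  seg2 <- call_roh_all(sim$geno[perm, ], sim$map)
  k1 <- seg1[order(seg1$sample_id, seg1$chrom, seg1$start_bp), ]
  k2 <- seg2[order(seg2$sample_id, seg2$chrom, seg2$start_bp), ]
  rownames(k1) <- rownames(k2) <- NULL
  expect_equal(k1, k2)
})

test_that("length classes are half-open with >16 open-ended", {
  expect_equal(classify_roh_length(65310000), ">16")
  expect_equal(classify_roh_length(2000000), "2-4")
  expect_equal(classify_roh_length(1500000), "1-2")
  expect_equal(classify_roh_length(c(4e6, 8e6, 16e6)),
               c("4-8", "8-16", ">16"))
  expect_error(classify_roh_length(999999), "1 Mbp")
})

test_that("summary statistics follow the animals-with-class convention", {
  segs <- data.frame(
    sample_id = c("A", "A", "B"),
    chrom = "1",
    start_bp = c(1e6, 5e6, 1e6),
    end_bp = c(2.5e6, 8e6, 2.2e6),
    n_hom = 30L, n_missing = 0L,
    length_bp = c(1.5e6, 3e6, 1.2e6))
  segs$length_class <- classify_roh_length(segs$length_bp)
  s <- summarize_roh(segs, c("A", "B", "C"))
  cs <- s$class_stats
  r12 <- cs[cs$class == "1-2", ]
  expect_equal(r12$n_animals, 2L)
  expect_equal(r12$mean, 1)           # one 1-2 Mbp ROH in each carrier
  r24 <- cs[cs$class == "2-4", ]
  expect_equal(r24$n_animals, 1L)     # only animal A
  expect_equal(s$mean_per_animal, 1)  # 3 segments / 3 animals
  expect_equal(s$grand_mean_length_mbp, (1.5 + 3 + 1.2) / 3)
  # single animal, single segment
  s1 <- summarize_roh(segs[3, ], "B")
  expect_equal(s1$grand_mean_length_mbp, 1.2)
  expect_warning(summarize_roh(segs[0, ], "A"), "no ROH")
})

test_that("summary totals agree with simulator truth totals", {
  cfg <- sim_config(n_samples = 15, n_chrom = 2, markers_per_chrom = 800,
                    missing_rate = 0, het_error_rate = 0, seed = 77)
  sim <- simulate_dataset(cfg)
  segs <- call_roh_all(sim$geno, sim$map)
  s <- summarize_roh(segs, rownames(sim$geno))
  expect_equal(s$n_segments, nrow(segs))
  expect_equal(sum(s$per_animal$n_roh), nrow(segs))
  expect_equal(sum(s$per_animal$total_mbp), sum(segs$length_bp) / 1e6)
  # per-class counts add up to the total count
  cls_cols <- paste0("n_", c("1-2", "2-4", "4-8", "8-16", ">16"))
  expect_equal(rowSums(s$per_animal[, cls_cols]), s$per_animal$n_roh,
               ignore_attr = TRUE)
})
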