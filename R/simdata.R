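# Forward pedigree simulator with identity-by-descent bookkeeping.
#
# Founder haplotypes carry unique labels; gametes are represented as
# piecewise-constant founder-origin tracks along each chromosome, so the
# true autozygous intervals of an individual are exactly the regions where
# its two gametes carry the same founder label. ROH and F_ROH measurements
# made downstream can then be scored against genuine IBD truth rather than
# against observed homozygosity.

#' Simulation configuration
#'
#' Defaults describe a cohort of 334 cows genotyped on a scaled-down chip:
#' 5 autosomes of 50 Mbp with 1000 markers each (20 markers/Mbp), a pool of
#' 40 founder haplotypes, 6 non-overlapping generations of random mating in
#' which a quarter of matings are between full sibs (creating autozygous
#' tracts across all five length classes), a genetic map of 1 cM/Mbp,
#' U-shaped allele frequencies truncated to \[0.05, 0.95\], first-order LD
#' between neighbouring markers, and light genotyping noise.
#'
#' @param n_samples cohort size (default 334).
#' @param n_chrom number of autosomes (default 5).
#' @param markers_per_chrom markers per autosome (default 1000).
#' @param chrom_length_bp autosome length in bp (default 5e7).
#' @param n_founder_haplotypes founder haplotype pool size (default 40).
#' @param generations non-overlapping generations after the founders
#'   (default 6).
#' @param inbred_mating_fraction fraction of parent pairs that are full
#'   sibs (default 0.25).
#' @param ld_rho probability a founder allele is copied from its left
#'   neighbour (first-order LD; default 0.3).
#' @param maf_range truncation bounds of the founder allele-frequency
#'   distribution (default `c(0.05, 0.95)`).
#' @param cm_per_mbp genetic map density (default 1).
#' @param missing_rate per-genotype missing probability (default 0.01).
#' @param het_error_rate probability a homozygous call is misread as a
#'   heterozygote (default 0.001).
#' @param include_x also emit an X chromosome (simulated as autosomal since
#'   all samples are female; default FALSE).
#' @param seed mandatory RNG seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 334L,
                       n_chrom = 5L,
                       markers_per_chrom = 1000L,
                       chrom_length_bp = 5e7,
                       n_founder_haplotypes = 40L,
                       generations = 6L,
                       inbred_mating_fraction = 0.25,
                       ld_rho = 0.3,
                       maf_range = c(0.05, 0.95),
                       cm_per_mbp = 1,
                       missing_rate = 0.01,
                       het_error_rate = 0.001,
                       include_x = FALSE,
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  rates <- c(inbred_mating_fraction, ld_rho, missing_rate, het_error_rate)
  if (any(rates < 0) || any(rates > 1)) stop("rates must lie in [0, 1]")
  if (n_founder_haplotypes < 4 || n_founder_haplotypes %% 2 != 0) {
    stop("n_founder_haplotypes must be an even number >= 4")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate the founder haplotype pool
#'
#' Allele frequencies are drawn from a Beta(0.5, 0.5) truncated to
#' `maf_range`; linkage disequilibrium is induced by a first-order copying
#' process: each allele equals its left neighbour with probability
#' `ld_rho`, otherwise it is drawn fresh at the marker's frequency.
#'
#' @param cfg a [sim_config()].
#' @return a list of class `sim_pool` with one element per chromosome:
#'   `list(pos, freq, H)` where `H` is haplotypes x markers in \{0, 1\}.
#' @export
simulate_founder_haplotypes <- function(cfg) {
  set.seed(cfg$seed)
  lo <- cfg$maf_range[1]; hi <- cfg$maf_range[2]
  n_hap <- cfg$n_founder_haplotypes
  chroms <- as.character(seq_len(cfg$n_chrom))
  if (cfg$include_x) chroms <- c(chroms, "X")
  pool <- lapply(chroms, function(ch) {
    m <- cfg$markers_per_chrom
    pos <- sort(sample.int(cfg$chrom_length_bp, m))
    freq <- stats::qbeta(stats::runif(m, stats::pbeta(lo, 0.5, 0.5),
                                      stats::pbeta(hi, 0.5, 0.5)), 0.5, 0.5)
    H <- matrix(0L, n_hap, m)
    H[, 1] <- stats::rbinom(n_hap, 1, freq[1])
    for (j in 2:m) {
      copy <- stats::runif(n_hap) < cfg$ld_rho
      fresh <- stats::rbinom(n_hap, 1, freq[j])
      H[, j] <- ifelse(copy, H[, j - 1], fresh)
    }
    list(pos = pos, freq = freq, H = H)
  })
  names(pool) <- chroms
  structure(pool, class = "sim_pool")
}

# A gamete on one chromosome: list(end = segment end positions (last = L),
# fid = founder haplotype id per segment). Segment k covers
# (end[k-1], end[k]] with end[0] = 0.

#' @keywords internal
gamete_slice <- function(g, from, to) {
  k1 <- findInterval(from - 1, g$end) + 1L
  k2 <- findInterval(to - 1, g$end) + 1L
  ends <- g$end[k1:k2]
  ends[length(ends)] <- to
  list(end = ends, fid = g$fid[k1:k2])
}

#' @keywords internal
gamete_simplify <- function(g) {
  if (length(g$fid) <= 1) return(g)
  keep <- c(g$fid[-1] != g$fid[-length(g$fid)], TRUE)
  list(end = g$end[keep], fid = g$fid[keep])
}

# Meiosis: recombine a parent's two gametes with Poisson crossovers.
#' @keywords internal
meiosis <- function(g1, g2, L, cm_per_mbp) {
  n_cross <- stats::rpois(1, L / 1e6 * cm_per_mbp / 100)
  phase <- stats::runif(1) < 0.5
  if (n_cross == 0) return(if (phase) g1 else g2)
  cuts <- sort(sample.int(L - 1, min(n_cross, L - 1)))
  bounds <- c(0, cuts, L)
  pieces <- vector("list", length(bounds) - 1)
  for (i in seq_along(pieces)) {
    src <- if (xor(phase, i %% 2 == 0)) g1 else g2
    pieces[[i]] <- gamete_slice(src, bounds[i] + 1, bounds[i + 1])
  }
  gamete_simplify(list(end = unlist(lapply(pieces, `[[`, "end")),
                       fid = unlist(lapply(pieces, `[[`, "fid"))))
}

# Shared-founder intervals of a gamete pair (the individual's autozygous
# truth on one chromosome).
#' @keywords internal
ibd_intervals <- function(g1, g2) {
  ends <- sort(unique(c(g1$end, g2$end)))
  starts <- c(1, utils::head(ends, -1) + 1)
  f1 <- g1$fid[findInterval(starts - 1, g1$end) + 1L]
  f2 <- g2$fid[findInterval(starts - 1, g2$end) + 1L]
  same <- f1 == f2
  if (!any(same)) {
    return(data.frame(start_bp = numeric(0), end_bp = numeric(0),
                      founder_id = integer(0)))
  }
  out <- data.frame(start_bp = starts[same], end_bp = ends[same],
                    founder_id = f1[same])
  # merge adjacent intervals with the same founder
  if (nrow(out) > 1) {
    glue <- out$start_bp[-1] == out$end_bp[-nrow(out)] + 1 &
      out$founder_id[-1] == out$founder_id[-nrow(out)]
    grp <- cumsum(c(TRUE, !glue))
    out <- data.frame(start_bp = tapply(out$start_bp, grp, min),
                      end_bp = tapply(out$end_bp, grp, max),
                      founder_id = tapply(out$founder_id, grp, `[`, 1))
  }
  rownames(out) <- NULL
  out
}

#' Simulate the pedigree and emit genotypes with IBD truth
#'
#' Founders receive disjoint haplotype pairs from the pool; each later
#' generation is produced by sampled parent pairs (full-sib pairs at the
#' configured fraction once sibships exist), with Poisson recombination at
#' `cm_per_mbp`. Genotyping missingness and heterozygote error are applied
#' last and are recorded nowhere in the truth.
#'
#' @param cfg a [sim_config()].
#' @param pool from [simulate_founder_haplotypes()].
#' @return `list(geno, map, truth, pool)`; `truth` holds per-sample
#'   autozygous intervals (`autozygous` data.frame), per-sample true
#'   autozygosity fractions (`autozygosity`), the simulated autosome length
#'   (`autosome_bp`), and empty slots for sweeps and QTL.
#' @export
simulate_pedigree <- function(cfg, pool) {
  set.seed(cfg$seed + 1L)
  n <- cfg$n_samples
  chroms <- names(pool)
  autosomes <- setdiff(chroms, "X")
  L <- cfg$chrom_length_bp

  n_founders <- cfg$n_founder_haplotypes %/% 2L
  new_ind <- function(f1, f2) {
    lapply(stats::setNames(chroms, chroms), function(ch) {
      list(list(end = L, fid = f1), list(end = L, fid = f2))
    })
  }
  popn <- lapply(seq_len(n_founders), function(i) new_ind(2L * i - 1L, 2L * i))
  sibship <- seq_len(n_founders)  # founders: all distinct sibships

  for (gen in seq_len(cfg$generations)) {
    n_prev <- length(popn)
    n_pairs <- max(2L, ceiling(n / 3))
    sib_tab <- split(seq_len(n_prev), sibship)
    sib_tab <- sib_tab[vapply(sib_tab, length, 1L) >= 2]
    pairs <- vector("list", n_pairs)
    for (k in seq_len(n_pairs)) {
      if (length(sib_tab) && stats::runif(1) < cfg$inbred_mating_fraction) {
        fam <- sib_tab[[sample.int(length(sib_tab), 1)]]
        pairs[[k]] <- sample(fam, 2)
      } else {
        pairs[[k]] <- sample.int(n_prev, 2)
      }
    }
    assign_pair <- rep_len(seq_len(n_pairs), n)
    child <- vector("list", n)
    for (i in seq_len(n)) {
      pr <- pairs[[assign_pair[i]]]
      mom <- popn[[pr[1]]]; dad <- popn[[pr[2]]]
      child[[i]] <- lapply(stats::setNames(chroms, chroms), function(ch) {
        list(meiosis(mom[[ch]][[1]], mom[[ch]][[2]], L, cfg$cm_per_mbp),
             meiosis(dad[[ch]][[1]], dad[[ch]][[2]], L, cfg$cm_per_mbp))
      })
    }
    popn <- child
    sibship <- assign_pair
  }

  sample_ids <- sprintf("cow%03d", seq_len(n))
  m_per <- cfg$markers_per_chrom
  geno <- matrix(NA_integer_, n, length(chroms) * m_per)
  truth_rows <- list()
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    pos <- pool[[ch]]$pos
    H <- pool[[ch]]$H
    cols <- (ci - 1L) * m_per + seq_len(m_per)
    for (i in seq_len(n)) {
      g1 <- popn[[i]][[ch]][[1]]; g2 <- popn[[i]][[ch]][[2]]
      f1 <- g1$fid[findInterval(pos - 1, g1$end) + 1L]
      f2 <- g2$fid[findInterval(pos - 1, g2$end) + 1L]
      a1 <- H[cbind(f1, seq_len(m_per))]
      a2 <- H[cbind(f2, seq_len(m_per))]
      geno[i, cols] <- a1 + a2
      if (ch %in% autosomes) {
        ib <- ibd_intervals(g1, g2)
        if (nrow(ib)) {
          truth_rows[[length(truth_rows) + 1L]] <- data.frame(
            sample_id = sample_ids[i], chrom = ch,
            start_bp = ib$start_bp, end_bp = ib$end_bp,
            founder_id = ib$founder_id, stringsAsFactors = FALSE)
        }
      }
    }
  }

  map <- marker_map(
    marker_id = unlist(lapply(chroms, function(ch)
      sprintf("snp_%s_%04d", ch, seq_len(m_per)))),
    chrom = rep(chroms, each = m_per),
    pos_bp = unlist(lapply(chroms, function(ch) pool[[ch]]$pos)),
    allele_a = "A", allele_b = "B")
  dimnames(geno) <- list(sample_ids, map$marker_id)

  # recode so dosage counts the minor allele (allele "B" := minor);
  # the flip state is kept so later edits can translate founder alleles
  p <- colMeans(geno) / 2
  flip <- p > 0.5
  geno[, flip] <- 2L - geno[, flip]

  # genotyping noise, applied last
  if (cfg$het_error_rate > 0) {
    hom <- !is.na(geno) & geno != 1L
    err <- hom & matrix(stats::runif(length(geno)) < cfg$het_error_rate,
                        nrow(geno))
    geno[err] <- 1L
  }
  if (cfg$missing_rate > 0) {
    mis <- matrix(stats::runif(length(geno)) < cfg$missing_rate, nrow(geno))
    geno[mis] <- NA_integer_
  }

  autos_bp <- length(autosomes) * L
  autoz <- if (length(truth_rows)) do.call(rbind, truth_rows)
  else data.frame(sample_id = character(0), chrom = character(0),
                  start_bp = numeric(0), end_bp = numeric(0),
                  founder_id = integer(0))
  frac <- vapply(sample_ids, function(s) {
    a <- autoz[autoz$sample_id == s, , drop = FALSE]
    sum(a$end_bp - a$start_bp + 1) / autos_bp
  }, numeric(1))
  truth <- list(autozygous = autoz,
                autozygosity = stats::setNames(frac, sample_ids),
                autosome_bp = autos_bp,
                sweeps = data.frame(chrom = character(0),
                                    start_bp = numeric(0),
                                    end_bp = numeric(0),
                                    carrier_fraction = numeric(0)),
                qtl = NULL)
  list(geno = geno, map = map, truth = truth, pool = pool,
       flipped = stats::setNames(flip, map$marker_id))
}

#' Plant a homozygosity island (selective sweep surrogate)
#'
#' In a random `carrier_fraction` of samples, both haplotypes across the
#' region are replaced by founder haplotype 1, producing a guaranteed
#' autozygous tract shared by all carriers. Truth intervals, autozygosity
#' fractions and the sweep registry are updated.
#'
#' @param sim a dataset from [simulate_pedigree()] (or [simulate_dataset()]).
#' @param chrom,start_bp,end_bp sweep region.
#' @param carrier_fraction fraction of samples made carriers.
#' @return the updated `sim` list.
#' @export
plant_sweep <- function(sim, chrom, start_bp, end_bp, carrier_fraction) {
  chrom <- normalize_chrom(chrom)
  if (!chrom %in% names(sim$pool)) stop("no such chromosome: ", chrom)
  if (end_bp - start_bp + 1 < 1e6) {
    warning("sweep region shorter than the minimum ROH length; ",
            "it may be undetectable")
  }
  pos_all <- sim$map$pos_bp
  in_reg <- sim$map$chrom == chrom & pos_all >= start_bp & pos_all <= end_bp
  if (!any(in_reg)) stop("sweep region contains no markers")
  n <- nrow(sim$geno)
  carriers <- sort(sample.int(n, round(carrier_fraction * n)))

  # founder haplotype 1 alleles at the member markers, translated into the
  # stored minor-allele column coding
  pool_ch <- sim$pool[[chrom]]
  midx <- match(sim$map$pos_bp[in_reg], pool_ch$pos)
  hap <- pool_ch$H[1L, midx]
  dos <- 2L * hap
  flipped <- sim$flipped[in_reg]
  dos[flipped] <- 2L - dos[flipped]
  sim$geno[carriers, in_reg] <- rep(dos, each = length(carriers))

  ids <- rownames(sim$geno)[carriers]
  add <- data.frame(sample_id = ids, chrom = chrom,
                    start_bp = start_bp, end_bp = end_bp,
                    founder_id = 1L, stringsAsFactors = FALSE)
  autoz <- rbind(sim$truth$autozygous, add)
  # re-merge per sample/chromosome (union of intervals)
  merged <- do.call(rbind, lapply(split(autoz, list(autoz$sample_id, autoz$chrom),
                                        drop = TRUE), function(s) {
    s <- s[order(s$start_bp), , drop = FALSE]
    st <- s$start_bp; en <- s$end_bp
    ks <- st[1]; ke <- en[1]
    if (nrow(s) > 1) for (i in 2:nrow(s)) {
      k <- length(ke)
      if (st[i] <= ke[k] + 1) ke[k] <- max(ke[k], en[i])
      else { ks <- c(ks, st[i]); ke <- c(ke, en[i]) }
    }
    data.frame(sample_id = s$sample_id[1], chrom = s$chrom[1],
               start_bp = ks, end_bp = ke,
               founder_id = NA_integer_, stringsAsFactors = FALSE)
  }))
  rownames(merged) <- NULL
  sim$truth$autozygous <- merged
  frac <- vapply(rownames(sim$geno), function(s) {
    a <- merged[merged$sample_id == s, , drop = FALSE]
    sum(a$end_bp - a$start_bp + 1) / sim$truth$autosome_bp
  }, numeric(1))
  sim$truth$autozygosity <- frac
  sim$truth$sweeps <- rbind(sim$truth$sweeps,
                            data.frame(chrom = chrom, start_bp = start_bp,
                                       end_bp = end_bp,
                                       carrier_fraction = carrier_fraction))
  sim
}

#' Simulate a quantitative trait with one additive QTL
#'
#' `y = mu + beta * dosage + u + e` with polygenic `u ~ N(0, sigma_g^2 K)`
#' and residual `e ~ N(0, sigma_e^2 I)`. The polygenic variance is derived
#' from `h2_polygenic` and `sigma_e2` as
#' `sigma_g2 = h2 / (1 - h2) * sigma_e2`.
#'
#' @param geno dosage matrix.
#' @param K kinship matrix (e.g. [compute_kinship()]).
#' @param qtl_marker marker ID or column index of the QTL (`NULL` for a
#'   purely polygenic trait).
#' @param beta additive effect per copy of the counted allele.
#' @param h2_polygenic polygenic heritability in `[0, 1)`.
#' @param sigma_e2 residual variance (> 0).
#' @param mu intercept (default 3.2, a milk protein-percentage scale).
#' @param seed RNG seed.
#' @return `list(y, components)` where `components` reports the realized
#'   QTL, polygenic and residual variances and the realized heritability.
#' @export
simulate_phenotype <- function(geno, K, qtl_marker, beta, h2_polygenic,
                               sigma_e2, mu = 3.2, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (sigma_e2 <= 0) stop("sigma_e2 must be positive")
  if (h2_polygenic < 0 || h2_polygenic >= 1) stop("h2_polygenic must be in [0, 1)")
  set.seed(seed)
  n <- nrow(geno)
  g <- numeric(n)
  if (!is.null(qtl_marker)) {
    j <- if (is.character(qtl_marker)) match(qtl_marker, colnames(geno))
    else as.integer(qtl_marker)
    if (is.na(j) || j < 1 || j > ncol(geno)) stop("QTL marker not found")
    d <- geno[, j]
    d[is.na(d)] <- mean(d, na.rm = TRUE)
    g <- beta * d
  }
  sigma_g2 <- h2_polygenic / (1 - h2_polygenic) * sigma_e2
  u <- if (sigma_g2 > 0) {
    ch <- chol(sigma_g2 * (K + diag(1e-8, n)))
    as.vector(crossprod(ch, stats::rnorm(n)))
  } else numeric(n)
  e <- stats::rnorm(n, sd = sqrt(sigma_e2))
  y <- mu + g + u + e
  list(y = stats::setNames(y, rownames(geno)),
       components = list(var_qtl = stats::var(g), var_g = stats::var(u),
                         var_e = stats::var(e), sigma_g2 = sigma_g2,
                         sigma_e2 = sigma_e2,
                         realized_h2 = (stats::var(g) + stats::var(u)) /
                           stats::var(y)))
}

#' Effect size for a target QTL variance share
#'
#' Returns the `beta` making the QTL explain `share` of the total trait
#' variance `var_total`, given the marker's dosage variance.
#'
#' @param dosage QTL marker dosages.
#' @param share target variance share in (0, 1).
#' @param var_total total trait variance the share refers to.
#' @return the additive effect size.
#' @export
qtl_beta_for_share <- function(dosage, share, var_total) {
  vd <- stats::var(dosage[!is.na(dosage)])
  if (vd <= 0) stop("QTL marker is monomorphic")
  sqrt(share * var_total / vd)
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: founder pool, pedigree, optional sweeps, optional
#' phenotype. Fully determined by `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param sweeps optional data.frame with `chrom`, `start_bp`, `end_bp`,
#'   `carrier_fraction` rows passed to [plant_sweep()].
#' @param qtl optional list with `marker` (ID or index), `beta` or `share`,
#'   `h2_polygenic`, `sigma_e2`, and optionally `mu`.
#' @return `list(geno, map, truth, pool, pheno, pheno_components)`.
#' @export
simulate_dataset <- function(cfg, sweeps = NULL, qtl = NULL) {
  pool <- simulate_founder_haplotypes(cfg)
  sim <- simulate_pedigree(cfg, pool)
  if (!is.null(sweeps)) {
    set.seed(cfg$seed + 2L)
    for (i in seq_len(nrow(sweeps))) {
      sim <- plant_sweep(sim, sweeps$chrom[i], sweeps$start_bp[i],
                         sweeps$end_bp[i], sweeps$carrier_fraction[i])
    }
  }
  sim$pheno <- NULL
  sim$pheno_components <- NULL
  if (!is.null(qtl)) {
    K <- compute_kinship(sim$geno)
    beta <- qtl$beta
    if (is.null(beta)) {
      j <- if (is.character(qtl$marker)) match(qtl$marker, colnames(sim$geno))
      else as.integer(qtl$marker)
      tot <- qtl$sigma_e2 / (1 - qtl$h2_polygenic) / (1 - qtl$share)
      beta <- qtl_beta_for_share(sim$geno[, j], qtl$share, tot)
    }
    ph <- simulate_phenotype(sim$geno, K, qtl$marker, beta,
                             qtl$h2_polygenic, qtl$sigma_e2,
                             mu = qtl$mu %||% 3.2, seed = cfg$seed + 3L)
    sim$pheno <- ph$y
    sim$pheno_components <- ph$components
    sim$truth$qtl <- list(marker = qtl$marker, beta = beta,
                          components = ph$components)
  }
  sim
}
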