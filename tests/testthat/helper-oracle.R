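# Independent oracles and fixture builders shared across the suite.

# Brute-force ROH oracle: enumerate every qualifying subinterval
# (homozygous endpoints, het/missing budgets, marker count, span), then
# select greedily from the left (leftmost start, then longest), dropping
# overlaps. Quadratic; only for small chromosomes.
oracle_roh <- function(dosage, pos, params) {
  n <- length(dosage)
  het <- !is.na(dosage) & dosage == 1L
  mis <- is.na(dosage)
  hom <- !het & !mis
  hom_idx <- which(hom)
  empty <- data.frame(start_bp = integer(0), end_bp = integer(0),
                      n_hom = integer(0), n_missing = integer(0))
  if (!length(hom_idx)) return(empty)
  c_hom <- cumsum(hom); c_het <- cumsum(het); c_mis <- cumsum(mis)
  quals <- list()
  for (i in hom_idx) {
    js <- hom_idx[hom_idx >= i]
    ok <- (c_het[js] - c_het[i] <= params$max_het) &
      (c_mis[js] - c_mis[i] <= params$max_missing) &
      (c_hom[js] - c_hom[i] + 1L >= params$min_snp) &
      (pos[js] - pos[i] + 1 >= params$min_length_bp)
    if (any(ok)) quals[[length(quals) + 1L]] <- cbind(i, js[ok])
  }
  if (!length(quals)) return(empty)
  Q <- do.call(rbind, quals)
  picks <- list()
  while (nrow(Q) > 0) {
    i0 <- min(Q[, 1])
    cand <- Q[Q[, 1] == i0, , drop = FALSE]
    pk <- cand[which.max(cand[, 2]), ]
    picks[[length(picks) + 1L]] <- pk
    Q <- Q[Q[, 1] > pk[2], , drop = FALSE]
  }
  P <- do.call(rbind, picks)
  data.frame(start_bp = pos[P[, 1]], end_bp = pos[P[, 2]],
             n_hom = c_hom[P[, 2]] - c_hom[P[, 1]] + 1L,
             n_missing = c_mis[P[, 2]] - c_mis[P[, 1]])
}

# Random single-chromosome genotype vector for ROH property tests.
random_chromosome <- function(n_markers, p_het = 0.2, p_miss = 0.05,
                              span_bp = 3e6) {
  dosage <- sample(c(0L, 1L, 2L, NA_integer_), n_markers, replace = TRUE,
                   prob = c((1 - p_het - p_miss) / 2, p_het,
                            (1 - p_het - p_miss) / 2, p_miss))
  pos <- sort(sample.int(span_bp, n_markers))
  list(dosage = dosage, pos = pos)
}

random_roh_params <- function() {
  roh_params(min_snp = sample(c(5L, 10L, 15L), 1),
             min_length_bp = sample(c(2e5, 5e5, 1e6), 1),
             max_het = sample(0:1, 1),
             max_missing = sample(0:6, 1))
}

# Direct REML log-likelihood, no eigendecomposition: builds V explicitly
# and uses solve(). Independent of the package's profiled/rotated path.
reml_ll_direct <- function(sg2, se2, y, X, K) {
  n <- length(y)
  V <- sg2 * K + se2 * diag(n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  b <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  as.numeric(-0.5 * (determinant(V, logarithm = TRUE)$modulus +
                       determinant(XtViX, logarithm = TRUE)$modulus +
                       t(r) %*% Vi %*% r))
}

# Zooming grid search of the direct REML surface over (sg2, se2).
reml_grid_oracle <- function(y, X, K, rounds = 4) {
  lo <- c(1e-4, 1e-4)
  hi <- c(5, 5) * stats::var(y)
  best <- NULL
  for (r in seq_len(rounds)) {
    g1 <- seq(lo[1], hi[1], length.out = 21)
    g2 <- seq(lo[2], hi[2], length.out = 21)
    ll <- outer(g1, g2, Vectorize(function(a, b)
      reml_ll_direct(a, b, y, X, K)))
    ix <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    best <- c(sg2 = g1[ix[1]], se2 = g2[ix[2]])
    st1 <- g1[2] - g1[1]; st2 <- g2[2] - g2[1]
    lo <- pmax(c(best[1] - st1, best[2] - st2), 1e-6)
    hi <- c(best[1] + st1, best[2] + st2)
  }
  best
}

# Tiny genotype fixture: n x m dosage matrix with a matching map.
toy_dataset <- function(n, m, p = NULL, chrom = "1", spacing = 50000L) {
  if (is.null(p)) p <- runif(m, 0.1, 0.5)
  geno <- matrix(as.integer(rbinom(n * m, 2, rep(p, each = n))), n, m,
                 dimnames = list(sprintf("s%03d", seq_len(n)),
                                 sprintf("m%04d", seq_len(m))))
  map <- marker_map(colnames(geno), rep(chrom, m),
                    spacing * seq_len(m), "A", "C")
  list(geno = geno, map = map)
}
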