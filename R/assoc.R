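# Single-marker association scans: kinship, PCA covariates, GLM (ordinary
# least squares) and MLM (kinship mixed model, EMMAX/P3D-style), with
# Bonferroni significance and genomic-control diagnostics.

#' VanRaden genomic relationship matrix (method 1)
#'
#' Columns are centred by twice the observed allele frequency and the
#' cross-product scaled by `2 * sum(p * (1 - p))`. Missing dosages are
#' mean-imputed per marker; monomorphic markers are dropped.
#'
#' @param geno dosage matrix (samples x markers).
#' @return symmetric n x n matrix with sample IDs as dimnames.
#' @export
compute_kinship <- function(geno) {
  x <- impute_col_mean(geno)
  p <- colMeans(x) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic markers; kinship undefined")
  x <- x[, poly, drop = FALSE]
  p <- p[poly]
  z <- sweep(x, 2, 2 * p)
  k <- tcrossprod(z) / (2 * sum(p * (1 - p)))
  dimnames(k) <- list(rownames(geno), rownames(geno))
  k
}

#' Principal components of the genotype matrix
#'
#' Eigenvectors of the standardized-genotype covariance (markers scaled by
#' `sqrt(2 p (1 - p))`). Signs are made deterministic by forcing the
#' largest-magnitude marker loading of each component positive.
#'
#' @param geno dosage matrix.
#' @param k number of components (default 3); `k = 0` returns an empty
#'   covariate block.
#' @return n x k matrix of scores.
#' @export
compute_pcs <- function(geno, k = 3L) {
  n <- nrow(geno)
  if (k >= n) stop("k must be smaller than the number of samples")
  if (k == 0L) {
    return(matrix(numeric(0), n, 0, dimnames = list(rownames(geno), NULL)))
  }
  x <- impute_col_mean(geno)
  p <- colMeans(x) / 2
  poly <- p > 0.001 & p < 0.999
  x <- x[, poly, drop = FALSE]
  p <- p[poly]
  z <- sweep(sweep(x, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  sv <- svd(z, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)] * flip, k, k)
  dimnames(scores) <- list(rownames(geno), paste0("PC", seq_len(k)))
  scores
}

#' Bonferroni significance threshold
#'
#' @param m_tested number of markers tested (>= 1).
#' @param alpha family-wise error rate (default 0.01).
#' @return `alpha / m_tested`.
#' @export
bonferroni_threshold <- function(m_tested, alpha = 0.01) {
  if (m_tested < 1) stop("m_tested must be >= 1")
  alpha / m_tested
}

#' Genomic inflation factor lambda
#'
#' Median of the one-d.f. chi-square quantiles of the p-values divided by
#' the null median 0.4549.
#'
#' @param p vector of p-values (NAs dropped).
#' @return lambda (about 1 for calibrated scans).
#' @export
lambda_gc <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) stop("no valid p-values")
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}

#' @keywords internal
check_covariates <- function(X0) {
  qrX <- qr(X0)
  if (qrX$rank < ncol(X0)) {
    bad <- colnames(X0)[qrX$pivot[(qrX$rank + 1):ncol(X0)]]
    stop("collinear covariate column(s): ", paste(bad, collapse = ", "))
  }
  invisible(qrX)
}

# Core vectorized scan in (possibly whitened) coordinates: OLS of y on
# [X0, g] per marker via Frisch-Waugh-Lovell residualization.
scan_ols <- function(G, y, X0) {
  n <- length(y)
  check_covariates(X0)
  P <- solve(crossprod(X0), crossprod(X0, cbind(y, G)))
  yres <- y - X0 %*% P[, 1, drop = FALSE]
  Gres <- G - X0 %*% P[, -1, drop = FALSE]
  gss <- colSums(Gres^2)
  untestable <- gss < 1e-12
  gss[untestable] <- NA_real_
  beta <- colSums(Gres * as.vector(yres)) / gss
  df <- n - ncol(X0) - 1L
  rss <- pmax(sum(yres^2) - beta^2 * gss, 0)
  sigma2 <- rss / df
  se <- sqrt(sigma2 / gss)
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df = df)
  p[p == 0] <- .Machine$double.xmin
  beta[untestable] <- 0
  se[untestable] <- NA_real_
  p[untestable] <- 1
  list(beta = beta, se = se, p = p, untestable = untestable)
}

#' @keywords internal
assoc_result <- function(map, fit, model, alpha, m_tested, extra = list()) {
  thr <- bonferroni_threshold(m_tested, alpha)
  res <- data.frame(marker_id = map$marker_id, chrom = map$chrom,
                    pos_bp = map$pos_bp,
                    beta = fit$beta, se = fit$se, p_value = fit$p,
                    untestable = fit$untestable,
                    significant = !fit$untestable & fit$p < thr,
                    model = model, stringsAsFactors = FALSE)
  out <- c(list(result = res,
                model = model,
                lambda_gc = lambda_gc(fit$p[!fit$untestable]),
                bonferroni_alpha = alpha,
                bonferroni_threshold = thr,
                m_tested = m_tested,
                significant_markers = res$marker_id[res$significant]),
           extra)
  class(out) <- "assoc_scan"
  out
}

#' @keywords internal
prep_scan <- function(geno, map, y, covariates) {
  validate_genotypes(geno, map)
  if (length(y) != nrow(geno)) stop("phenotype length does not match samples")
  keep <- !is.na(y)
  if (sum(keep) < 3) stop("fewer than 3 non-missing phenotypes")
  y <- y[keep]
  if (stats::var(y) == 0) stop("phenotype is constant")
  G <- impute_col_mean(geno[keep, , drop = FALSE])
  X0 <- cbind(`(Intercept)` = rep(1, sum(keep)))
  if (!is.null(covariates) && ncol(covariates) > 0) {
    cv <- as.matrix(covariates)[keep, , drop = FALSE]
    colnames(cv) <- colnames(covariates) %||% paste0("C", seq_len(ncol(cv)))
    X0 <- cbind(X0, cv)
  }
  list(G = G, y = y, X0 = X0, keep = keep)
}

#' GLM association scan
#'
#' Per-marker ordinary least squares of the trait on intercept +
#' covariates + dosage with a two-sided t-test on the dosage coefficient.
#' Samples with missing phenotype are dropped; missing dosages are
#' mean-imputed per marker. Monomorphic markers are flagged untestable
#' (beta 0, p 1).
#'
#' @param geno dosage matrix.
#' @param map marker map.
#' @param y numeric trait vector aligned to the samples.
#' @param covariates optional n x c numeric matrix (e.g. PC scores).
#' @param alpha Bonferroni family-wise level (default 0.01).
#' @return an `assoc_scan` list: per-marker `result` data.frame plus
#'   `lambda_gc`, `bonferroni_threshold`, `significant_markers`.
#' @export
glm_scan <- function(geno, map, y, covariates = NULL, alpha = 0.01) {
  pr <- prep_scan(geno, map, y, covariates)
  fit <- scan_ols(pr$G, pr$y, pr$X0)
  assoc_result(map, fit, "glm", alpha, m_tested = ncol(pr$G))
}

# Profile REML log-likelihood in the eigenbasis of K, as a function of
# delta = sigma_e^2 / sigma_g^2. d are eigenvalues of K; Ystar/Xstar are
# rotated responses/covariates.
reml_profile_ll <- function(log10_delta, d, ystar, Xstar) {
  delta <- 10^log10_delta
  w <- 1 / (d + delta)
  sw <- sqrt(w)
  Xw <- Xstar * sw
  yw <- ystar * sw
  XtX <- crossprod(Xw)
  b <- solve(XtX, crossprod(Xw, yw))
  r <- yw - Xw %*% b
  n <- length(ystar); p <- ncol(Xstar)
  sg2 <- sum(r^2) / (n - p)
  -0.5 * ((n - p) * log(sg2) - sum(log(w)) +
            determinant(XtX, logarithm = TRUE)$modulus[1] + (n - p))
}

#' @keywords internal
reml_null <- function(d, ystar, Xstar, grid = seq(-5, 5, by = 0.1)) {
  ll <- vapply(grid, reml_profile_ll, numeric(1),
               d = d, ystar = ystar, Xstar = Xstar)
  if (any(!is.finite(ll))) stop("REML likelihood not finite on the grid")
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(reml_profile_ll, c(lo, hi), d = d, ystar = ystar,
                         Xstar = Xstar, maximum = TRUE, tol = 1e-8)
  ld <- if (opt$objective >= ll[i]) opt$maximum else grid[i]
  delta <- 10^ld
  w <- 1 / (d + delta)
  sw <- sqrt(w)
  Xw <- Xstar * sw; yw <- ystar * sw
  b <- solve(crossprod(Xw), crossprod(Xw, yw))
  n <- length(ystar); p <- ncol(Xstar)
  sg2 <- sum((yw - Xw %*% b)^2) / (n - p)
  list(log10_delta = ld, delta = delta, sigma_g2 = sg2,
       sigma_e2 = delta * sg2,
       boundary_high = ld >= max(grid) - 1e-6)
}

#' MLM association scan (kinship mixed model)
#'
#' Fits `y = X b + g beta + u + e` with `u ~ N(0, sigma_g^2 K)` and
#' `e ~ N(0, sigma_e^2 I)`. Variance components are estimated once by REML
#' on the null model (eigendecomposition of K, 1-D search over
#' `log10(sigma_e^2 / sigma_g^2)` on \[-5, 5\] with golden-section
#' refinement), then fixed for all marker tests (P3D/EMMAX). When the REML
#' optimum sits at the upper variance-ratio boundary the polygenic
#' component is taken as zero and the scan collapses to the GLM exactly.
#' `exact_reml = TRUE` re-estimates the components per marker instead.
#'
#' @inheritParams glm_scan
#' @param K kinship matrix aligned to the samples.
#' @param exact_reml per-marker REML instead of P3D (slow; default FALSE).
#' @return `list(scan = assoc_scan, vc = variance components)`; `vc` has
#'   `sigma_g2`, `sigma_e2` and `h2 = sigma_g2 / (sigma_g2 + sigma_e2)`.
#' @export
mlm_scan <- function(geno, map, y, K, covariates = NULL, alpha = 0.01,
                     exact_reml = FALSE) {
  pr <- prep_scan(geno, map, y, covariates)
  Ks <- K[pr$keep, pr$keep, drop = FALSE]
  if (max(abs(Ks - t(Ks))) > 1e-8) stop("kinship matrix is not symmetric")
  eig <- eigen(Ks, symmetric = TRUE)
  if (min(eig$values) < -1e-8 * max(abs(eig$values))) {
    stop("kinship matrix is not positive semidefinite beyond tolerance")
  }
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  ystar <- as.vector(crossprod(U, pr$y))
  Xstar <- crossprod(U, pr$X0)
  null <- reml_null(d, ystar, Xstar)

  if (null$boundary_high) {
    # polygenic variance indistinguishable from zero: exact GLM limit
    fit <- scan_ols(pr$G, pr$y, pr$X0)
    vc <- list(sigma_g2 = 0, sigma_e2 = stats::var(pr$y), h2 = 0,
               delta = Inf)
    return(list(scan = assoc_result(map, fit, "mlm", alpha, ncol(pr$G)),
                vc = vc))
  }

  if (!exact_reml) {
    sw <- sqrt(1 / (d + null$delta))
    fit <- scan_ols(crossprod(U, pr$G) * sw, ystar * sw, Xstar * sw)
  } else {
    Gstar <- crossprod(U, pr$G)
    m <- ncol(Gstar)
    beta <- se <- p <- numeric(m)
    untestable <- logical(m)
    for (j in seq_len(m)) {
      Xj <- cbind(Xstar, Gstar[, j])
      if (qr(Xj)$rank < ncol(Xj)) {
        beta[j] <- 0; se[j] <- NA; p[j] <- 1; untestable[j] <- TRUE
        next
      }
      nj <- reml_null(d, ystar, Xj)
      sw <- sqrt(1 / (d + nj$delta))
      f <- scan_ols(Gstar[, j, drop = FALSE] * sw, ystar * sw, Xstar * sw)
      beta[j] <- f$beta; se[j] <- f$se; p[j] <- f$p
      untestable[j] <- f$untestable
    }
    fit <- list(beta = beta, se = se, p = p, untestable = untestable)
  }
  vc <- list(sigma_g2 = null$sigma_g2, sigma_e2 = null$sigma_e2,
             h2 = null$sigma_g2 / (null$sigma_g2 + null$sigma_e2),
             delta = null$delta)
  list(scan = assoc_result(map, fit, "mlm", alpha, ncol(pr$G)), vc = vc)
}

#' Trait summary stratified by genotype
#'
#' Groups samples by genotype at one biallelic marker and reports n, mean
#' and SD of the trait per group. Group labels use the allele pair
#' (`allele_a` homozygote, heterozygote, `allele_b` homozygote); missing
#' genotypes form the `"undefined"` group.
#'
#' @param dosage dosage vector for one marker (counts of `allele_b`).
#' @param alleles character vector `c(allele_a, allele_b)`.
#' @param y trait values aligned to `dosage`.
#' @return data.frame with `genotype`, `n`, `mean`, `sd`.
#' @export
genotype_trait_summary <- function(dosage, alleles, y) {
  a <- alleles[1]; b <- alleles[2]
  lab <- c(paste0(a, a), paste0(b, a), paste0(b, b))
  grp <- ifelse(is.na(dosage), "undefined", lab[dosage + 1L])
  grp <- factor(grp, levels = c(lab, "undefined"))
  out <- do.call(rbind, lapply(levels(grp), function(gl) {
    yy <- y[grp == gl & !is.na(y)]
    if (!length(yy)) return(NULL)
    data.frame(genotype = gl, n = length(yy), mean = mean(yy),
               sd = if (length(yy) > 1) stats::sd(yy) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write an association scan as TSV
#'
#' @param scan an `assoc_scan` (from [glm_scan()] or `mlm_scan()$scan`).
#' @param geno dosage matrix used for the scan (for per-marker MAF).
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_assoc <- function(scan, geno, path) {
  res <- scan$result
  res$maf <- maf(geno)[match(res$marker_id, colnames(geno))]
  utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
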