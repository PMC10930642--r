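# Sample/marker quality control and the two analysis marker sets.
#
# Two profiles reproduce the study design:
#   "gwas": sample filter -> marker call rate -> biallelic -> MAF -> LD prune;
#           autosomes + X retained.
#   "roh":  sample filter -> marker call rate -> biallelic; no MAF filter,
#           no LD pruning; autosomes only (X dropped).

#' Quality-control configuration
#'
#' @param sample_call_rate_min samples with call rate \eqn{\le} this are
#'   removed (default 0.90; the boundary itself is removed).
#' @param marker_call_rate_min markers with call rate below this are removed
#'   (default 0.95; the boundary itself is kept).
#' @param maf_min minimum minor allele frequency (default 0.01; GWAS profile
#'   only).
#' @param ld_r2_max,ld_window_snps,ld_window_step windowed LD-pruning
#'   parameters (defaults 0.5 / 50 / 5; GWAS profile only).
#' @param profile `"gwas"` or `"roh"`.
#' @return a list of class `qc_config`.
#' @export
qc_config <- function(sample_call_rate_min = 0.90,
                      marker_call_rate_min = 0.95,
                      maf_min = 0.01,
                      ld_r2_max = 0.5,
                      ld_window_snps = 50L,
                      ld_window_step = 5L,
                      profile = c("gwas", "roh")) {
  profile <- match.arg(profile)
  fr <- c(sample_call_rate_min, marker_call_rate_min, maf_min, ld_r2_max)
  if (any(fr < 0) || any(fr > 1)) stop("QC fractions must lie in [0, 1]")
  structure(list(sample_call_rate_min = sample_call_rate_min,
                 marker_call_rate_min = marker_call_rate_min,
                 maf_min = maf_min,
                 ld_r2_max = ld_r2_max,
                 ld_window_snps = as.integer(ld_window_snps),
                 ld_window_step = as.integer(ld_window_step),
                 profile = profile),
            class = "qc_config")
}

#' Minor allele frequency per marker
#'
#' Missing calls are excluded from the denominator. Because dosages count
#' one declared allele, MAF is `min(p, 1 - p)` of its frequency.
#'
#' @param geno dosage matrix (or a single dosage vector).
#' @return numeric vector of per-marker MAF (`NaN` where all calls missing).
#' @export
maf <- function(geno) {
  if (is.null(dim(geno))) geno <- matrix(geno, ncol = 1)
  p <- colMeans(geno, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Remove low-call-rate samples
#'
#' A sample is removed when its genotyping success rate is less than or
#' equal to `threshold` (strict "keep if > threshold").
#'
#' @param geno dosage matrix.
#' @param threshold call-rate boundary in `[0, 1]` (default 0.90).
#' @return `list(geno = filtered matrix, removed = character IDs)`.
#' @export
sample_call_rate_filter <- function(geno, threshold = 0.90) {
  stopifnot(threshold >= 0, threshold <= 1)
  cr <- rowMeans(!is.na(geno))
  keep <- cr > threshold
  if (!any(keep)) stop("all samples removed by call-rate filter")
  list(geno = geno[keep, , drop = FALSE],
       removed = rownames(geno)[!keep] %||% which(!keep))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Marker filters: call rate, biallelic, MAF
#'
#' Markers are kept iff call rate \eqn{\ge} `call_rate_min`, at most two
#' observed alleles, and MAF \eqn{\ge} `maf_min`. Removal reasons are
#' tallied with precedence call rate, then multi-allelic, then MAF.
#'
#' @param geno dosage matrix.
#' @param map marker map (an `n_alleles` column, if present, flags
#'   multi-allelic markers).
#' @param call_rate_min keep boundary, inclusive (default 0.95).
#' @param maf_min minimum MAF (default 0.01); set `NA` to skip.
#' @param biallelic_only drop markers with > 2 observed alleles.
#' @return `list(geno, map, removals = named counts, removed_ids = list)`.
#' @export
marker_filter <- function(geno, map, call_rate_min = 0.95, maf_min = 0.01,
                          biallelic_only = TRUE) {
  validate_genotypes(geno, map)
  cr <- colMeans(!is.na(geno))
  fail_cr <- cr < call_rate_min
  n_all <- if ("n_alleles" %in% names(map)) map$n_alleles else rep(2L, nrow(map))
  fail_multi <- biallelic_only & n_all > 2L & !fail_cr
  f <- maf(geno)
  fail_maf <- if (is.na(maf_min)) rep(FALSE, nrow(map)) else
    (!is.nan(f) & f < maf_min) & !fail_cr & !fail_multi
  keep <- !(fail_cr | fail_multi | fail_maf)
  if (!any(keep)) stop("no markers survive marker filters")
  list(geno = geno[, keep, drop = FALSE],
       map = map[keep, , drop = FALSE],
       removals = c(call_rate = sum(fail_cr),
                    multiallelic = sum(fail_multi),
                    maf = sum(fail_maf)),
       removed_ids = list(call_rate = map$marker_id[fail_cr],
                          multiallelic = map$marker_id[fail_multi],
                          maf = map$marker_id[fail_maf]))
}

#' @keywords internal
impute_col_mean <- function(geno) {
  mu <- colMeans(geno, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(geno), arr.ind = TRUE)
  if (nrow(idx)) geno[idx] <- mu[idx[, 2]]
  geno
}

#' Windowed LD pruning
#'
#' Greedy `indep-pairwise`-style pruning per chromosome: within each window
#' of `window_snps` markers, while any retained pair has squared genotype
#' correlation above `r2_max`, the member with the lower MAF is dropped
#' (tie: the later position); the window then slides by `step` markers.
#' Missing dosages are mean-imputed for the correlation only.
#'
#' @param geno dosage matrix.
#' @param map marker map.
#' @param r2_max prune boundary, exclusive keep (default 0.5).
#' @param window_snps window size in markers (default 50).
#' @param step slide in markers (default 5).
#' @return `list(kept = marker IDs, removed = marker IDs)`.
#' @export
ld_prune <- function(geno, map, r2_max = 0.5, window_snps = 50L, step = 5L) {
  validate_genotypes(geno, map)
  keep <- rep(TRUE, nrow(map))
  x <- impute_col_mean(geno)
  mafs <- maf(geno)
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    if (length(idx) < 2) next
    ws <- 1L
    while (ws <= length(idx)) {
      w <- idx[ws:min(ws + window_snps - 1L, length(idx))]
      repeat {
        act <- w[keep[w]]
        if (length(act) < 2) break
        cc <- suppressWarnings(stats::cor(x[, act, drop = FALSE]))
        cc[!is.finite(cc)] <- 0
        r2 <- cc^2
        diag(r2) <- 0
        if (max(r2) <= r2_max) break
        p <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
        i <- act[p[1]]; j <- act[p[2]]
        drop_id <- if (mafs[i] < mafs[j]) i
        else if (mafs[j] < mafs[i]) j
        else max(i, j)  # tie: later position
        keep[drop_id] <- FALSE
      }
      if (ws + window_snps - 1L >= length(idx)) break
      ws <- ws + step
    }
  }
  list(kept = map$marker_id[keep], removed = map$marker_id[!keep])
}

#' Build an analysis-ready dataset under a QC profile
#'
#' Applies the sample filter, chromosome selection, marker filters and
#' (GWAS profile only) MAF filter and LD pruning, returning the filtered
#' data plus an accounting report.
#'
#' @param geno dosage matrix.
#' @param map marker map.
#' @param cfg a [qc_config()].
#' @return `list(geno, map, report)`; `report` is a list with sample and
#'   marker in/out counts and per-filter removal tallies.
#' @export
build_dataset <- function(geno, map, cfg) {
  stopifnot(inherits(cfg, "qc_config"))
  validate_genotypes(geno, map)
  samples_in <- nrow(geno)
  markers_in <- nrow(map)

  sf <- sample_call_rate_filter(geno, cfg$sample_call_rate_min)
  geno <- sf$geno

  keep_chrom <- if (cfg$profile == "roh") map$chrom != "X"
  else map$chrom %in% c(as.character(1:29), "X")
  removed_sex <- sum(!keep_chrom)
  geno <- geno[, keep_chrom, drop = FALSE]
  map <- map[keep_chrom, , drop = FALSE]

  mf <- marker_filter(geno, map,
                      call_rate_min = cfg$marker_call_rate_min,
                      maf_min = if (cfg$profile == "gwas") cfg$maf_min else NA,
                      biallelic_only = TRUE)
  geno <- mf$geno; map <- mf$map
  removals <- c(sex_chrom = removed_sex, mf$removals, ld = 0L)

  if (cfg$profile == "gwas") {
    lp <- ld_prune(geno, map, cfg$ld_r2_max, cfg$ld_window_snps,
                   cfg$ld_window_step)
    keep <- map$marker_id %in% lp$kept
    removals["ld"] <- sum(!keep)
    geno <- geno[, keep, drop = FALSE]
    map <- map[keep, , drop = FALSE]
  }

  report <- list(profile = cfg$profile,
                 samples_in = samples_in,
                 samples_out = nrow(geno),
                 samples_removed = length(sf$removed),
                 markers_in = markers_in,
                 markers_out = nrow(map),
                 removals = removals)
  stopifnot(report$markers_out == markers_in - sum(removals))
  list(geno = geno, map = map, report = report)
}
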