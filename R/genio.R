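# PLINK text/binary genotype I/O and phenotype tables.
#
# The pipeline's central objects are deliberately plain:
#   * genotype matrix: integer matrix, samples x markers, entries 0/1/2/NA
#     counting copies of allele_b (the minor allele at read time);
#     rownames = sample IDs, colnames = marker IDs.
#   * marker map: data.frame(marker_id, chrom, pos_bp, allele_a, allele_b
#     [, n_alleles]) sorted by (chrom, pos_bp).

MISSING_DOSAGE <- NA_integer_

#' Normalize chromosome labels
#'
#' Strips any `"chr"` prefix and maps the bovine sex-chromosome code `"30"`
#' to `"X"`. Autosomes are `"1"`..`"29"` (BTA1--BTA29).
#'
#' @param chrom character or numeric vector of chromosome labels.
#' @return character vector of normalized labels.
#' @export
normalize_chrom <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  x[x %in% c("30", "x")] <- "X"
  x
}

#' @keywords internal
chrom_rank <- function(chrom) {
  n <- suppressWarnings(as.numeric(chrom))
  n[chrom == "X"] <- 1000
  if (anyNA(n)) stop("unknown chromosome label(s): ",
                     paste(unique(chrom[is.na(n)]), collapse = ", "))
  n
}

#' Construct and validate a marker map
#'
#' @param marker_id unique marker identifiers.
#' @param chrom chromosome labels (normalized via [normalize_chrom()]).
#' @param pos_bp 1-based physical positions, strictly increasing within a
#'   chromosome.
#' @param allele_a,allele_b allele labels; `allele_b` is the allele counted
#'   by the dosage matrix (minor allele at read time; `"0"` if unobserved).
#' @param n_alleles optional observed allele count per marker (used by QC to
#'   flag multi-allelic markers).
#' @return a `data.frame` with one row per marker.
#' @export
marker_map <- function(marker_id, chrom, pos_bp, allele_a = "A", allele_b = "B",
                       n_alleles = NULL) {
  chrom <- normalize_chrom(chrom)
  m <- data.frame(marker_id = as.character(marker_id),
                  chrom = chrom,
                  pos_bp = as.integer(pos_bp),
                  allele_a = as.character(allele_a),
                  allele_b = as.character(allele_b),
                  stringsAsFactors = FALSE)
  if (!is.null(n_alleles)) m$n_alleles <- as.integer(n_alleles)
  validate_marker_map(m)
  m
}

#' @keywords internal
validate_marker_map <- function(m) {
  if (anyDuplicated(m$marker_id)) {
    stop("duplicate marker_id: ",
         paste(unique(m$marker_id[duplicated(m$marker_id)]), collapse = ", "))
  }
  if (any(m$pos_bp < 1L)) stop("pos_bp must be >= 1")
  o <- order(chrom_rank(m$chrom), m$pos_bp)
  if (!identical(o, seq_len(nrow(m)))) {
    stop("markers must be sorted by (chrom, pos_bp)")
  }
  for (ch in unique(m$chrom)) {
    p <- m$pos_bp[m$chrom == ch]
    if (anyDuplicated(p)) stop("duplicate position on chromosome ", ch)
  }
  invisible(m)
}

#' @keywords internal
validate_genotypes <- function(geno, map) {
  stopifnot(is.matrix(geno))
  if (ncol(geno) != nrow(map)) {
    stop("genotype matrix has ", ncol(geno), " columns but map has ",
         nrow(map), " markers")
  }
  v <- geno[!is.na(geno)]
  if (length(v) && (any(v < 0L) || any(v > 2L))) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  invisible(geno)
}

#' Read PLINK text genotypes (.ped/.map)
#'
#' Dosage is coded as the count of the minor allele per marker (ties at
#' frequency 0.5 broken toward the lexicographically smaller allele);
#' `0 0` genotypes become missing. Markers with more than two observed
#' alleles get all-missing dosages and `n_alleles` recorded in the map so
#' QC can remove them.
#'
#' @param ped_path path to the `.ped` file (6 ID columns + 2 alleles/marker).
#' @param map_path path to the 4-column `.map` file.
#' @return `list(geno = matrix, map = data.frame)`.
#' @export
read_plink_text <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("no such file: ", ped_path)
  if (!file.exists(map_path)) stop("no such file: ", map_path)
  map_raw <- utils::read.table(map_path, header = FALSE,
                               colClasses = "character")
  if (ncol(map_raw) != 4) stop(".map must have 4 columns, found ", ncol(map_raw))
  m <- nrow(map_raw)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * m
  for (i in seq_along(fields)) {
    if (length(fields[[i]]) != want) {
      stop(".ped line ", i, ": expected ", want, " fields, found ",
           length(fields[[i]]))
    }
  }
  n <- length(fields)
  ped <- matrix(unlist(fields), nrow = n, byrow = TRUE)
  sample_ids <- ped[, 2]
  a1 <- ped[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  a2 <- ped[, 6L + 2L * seq_len(m), drop = FALSE]

  geno <- matrix(NA_integer_, n, m)
  allele_a <- allele_b <- character(m)
  n_alleles <- integer(m)
  for (j in seq_len(m)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    miss <- x1 == "0" | x2 == "0"
    obs <- c(x1[!miss], x2[!miss])
    alleles <- sort(unique(obs))
    n_alleles[j] <- length(alleles)
    if (length(alleles) > 2L) {
      allele_a[j] <- alleles[1]; allele_b[j] <- alleles[2]
      next  # left all-missing; QC removes as multi-allelic
    }
    if (length(alleles) == 0L) {
      allele_a[j] <- "0"; allele_b[j] <- "0"
      next
    }
    if (length(alleles) == 1L) {
      allele_a[j] <- alleles[1]; allele_b[j] <- "0"
      geno[, j] <- ifelse(miss, NA_integer_, 0L)
      next
    }
    cnt <- c(sum(obs == alleles[1]), sum(obs == alleles[2]))
    # minor allele is allele_b; tie -> lexicographically smaller (alleles[1])
    bi <- if (cnt[1] <= cnt[2]) 1L else 2L
    allele_b[j] <- alleles[bi]; allele_a[j] <- alleles[-bi]
    d <- (x1 == allele_b[j]) + (x2 == allele_b[j])
    d[miss] <- NA_integer_
    geno[, j] <- as.integer(d)
  }

  map <- marker_map(map_raw[[2]], map_raw[[1]], as.integer(map_raw[[4]]),
                    allele_a, allele_b, n_alleles = n_alleles)
  dimnames(geno) <- list(sample_ids, map$marker_id)
  list(geno = geno, map = map)
}

PLINK_BED_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))

#' Write PLINK binary genotypes (.bed/.bim/.fam)
#'
#' SNP-major layout; A1 in the `.bim` is `allele_b` (the counted allele),
#' A2 is `allele_a`. All samples are written as females (sex code 2),
#' matching an all-cow cohort.
#'
#' @param geno samples x markers dosage matrix.
#' @param map marker map as from [marker_map()].
#' @param out_prefix output path prefix; `.bed`, `.bim`, `.fam` are appended.
#' @return invisibly, the three file paths.
#' @export
write_plink_bed <- function(geno, map, out_prefix) {
  validate_genotypes(geno, map)
  if (nrow(map) == 0L) stop("empty marker set")
  n <- nrow(geno)
  bed <- paste0(out_prefix, ".bed")
  bim <- paste0(out_prefix, ".bim")
  fam <- paste0(out_prefix, ".fam")

  ids <- rownames(geno)
  if (is.null(ids)) ids <- paste0("sample", seq_len(n))
  utils::write.table(
    data.frame(ids, ids, 0L, 0L, 2L, -9L),
    fam, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  utils::write.table(
    data.frame(map$chrom, map$marker_id, 0L, map$pos_bp,
               map$allele_b, map$allele_a),
    bim, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")

  # 2-bit codes: 00 hom A1 (dosage 2), 01 missing, 10 het, 11 hom A2 (dosage 0)
  code <- matrix(3L, n, ncol(geno))
  code[geno == 2L] <- 0L
  code[is.na(geno)] <- 1L
  code[geno == 1L] <- 2L
  n4 <- 4L * ceiling(n / 4L)
  if (n4 > n) code <- rbind(code, matrix(0L, n4 - n, ncol(code)))
  i <- seq(1L, n4, by = 4L)
  bytes <- code[i, , drop = FALSE] +
    4L * code[i + 1L, , drop = FALSE] +
    16L * code[i + 2L, , drop = FALSE] +
    64L * code[i + 3L, , drop = FALSE]
  con <- file(bed, "wb")
  on.exit(close(con))
  writeBin(PLINK_BED_MAGIC, con)
  writeBin(as.raw(as.vector(bytes)), con)
  invisible(c(bed = bed, bim = bim, fam = fam))
}

#' Read PLINK binary genotypes (.bed/.bim/.fam)
#'
#' Dosage counts the A1 allele of the `.bim` (column 5), so data written by
#' [write_plink_bed()] round-trips bit-identically.
#'
#' @param bed,bim,fam paths to the three PLINK files.
#' @return `list(geno = matrix, map = data.frame)`.
#' @export
read_plink_bed <- function(bed, bim, fam) {
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("no such file: ", f)
  fam_df <- utils::read.table(fam, header = FALSE, colClasses = "character")
  bim_df <- utils::read.table(bim, header = FALSE, colClasses = "character")
  n <- nrow(fam_df)
  m <- nrow(bim_df)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3L || !identical(raw[1:3], PLINK_BED_MAGIC)) {
    stop("not SNP-major PLINK bed")
  }
  bpm <- ceiling(n / 4)
  body <- raw[-(1:3)]
  if (length(body) != bpm * m) {
    stop("truncated .bed: expected ", bpm * m, " data bytes, found ",
         length(body))
  }
  ints <- as.integer(body)
  codes <- rbind(ints %% 4L, (ints %/% 4L) %% 4L,
                 (ints %/% 16L) %% 4L, (ints %/% 64L) %% 4L)
  dim(codes) <- c(4L * bpm, m)
  codes <- codes[seq_len(n), , drop = FALSE]
  lut <- c(2L, NA_integer_, 1L, 0L)  # code 0..3 -> dosage of A1
  geno <- matrix(lut[codes + 1L], n, m)
  map <- marker_map(bim_df[[2]], bim_df[[1]], as.integer(bim_df[[4]]),
                    allele_a = bim_df[[6]], allele_b = bim_df[[5]])
  dimnames(geno) <- list(fam_df[[2]], map$marker_id)
  list(geno = geno, map = map)
}

#' Declared milk-trait dictionary
#'
#' Twelve lactation traits: total and 305-day-adjusted milk yield, protein
#' concentration and fat concentration, each for lactations 1 and 2.
#'
#' @return character vector of the twelve trait names.
#' @export
milk_trait_names <- function() {
  c("milk_yield_l1", "milk_yield_l2",
    "protein_pct_l1", "protein_pct_l2",
    "fat_pct_l1", "fat_pct_l2",
    "milk_yield_305d_l1", "milk_yield_305d_l2",
    "protein_pct_305d_l1", "protein_pct_305d_l2",
    "fat_pct_305d_l1", "fat_pct_305d_l2")
}

#' Read a phenotype table
#'
#' Tab/whitespace-delimited with a header; first column is the sample ID,
#' remaining columns are trait values (`NA` for missing). Trait columns not
#' in `trait_names` are kept with a warning. If `samples` is given, an
#' `in_genotypes` flag is added and an error raised when no phenotyped
#' sample overlaps the genotyped ones.
#'
#' @param path file path.
#' @param trait_names declared trait dictionary
#'   (default [milk_trait_names()]).
#' @param samples optional genotyped sample IDs to check overlap against.
#' @return data.frame with `sample_id`, trait columns, and optionally
#'   `in_genotypes`.
#' @export
read_phenotypes <- function(path, trait_names = milk_trait_names(),
                            samples = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ph <- utils::read.table(path, header = TRUE, na.strings = c("NA", "."),
                          stringsAsFactors = FALSE)
  names(ph)[1] <- "sample_id"
  ph$sample_id <- as.character(ph$sample_id)
  if (anyDuplicated(ph$sample_id)) stop("duplicate sample_id in phenotype table")
  extra <- setdiff(names(ph)[-1], trait_names)
  if (length(extra)) {
    warning("trait column(s) not in declared dictionary: ",
            paste(extra, collapse = ", "))
  }
  if (!is.null(samples)) {
    ph$in_genotypes <- ph$sample_id %in% samples
    if (!any(ph$in_genotypes)) {
      stop("no phenotyped sample overlaps the genotyped samples")
    }
  }
  ph
}
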