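# Runs-of-homozygosity detection under a consecutive-homozygote rule.
#
# A ROH is a run of markers containing no heterozygote (beyond max_het),
# at most max_missing unread calls, at least min_snp homozygous calls, and
# spanning at least min_length_bp. Runs begin and end on homozygous markers.
# Calling is greedy left-to-right: the leftmost homozygous start admitting a
# qualifying run is extended as far as the heterozygote/missing budgets
# allow, the run is emitted, and scanning resumes after it — so the segments
# of one sample on one chromosome never overlap.

ROH_CLASS_LABELS <- c("1-2", "2-4", "4-8", "8-16", ">16")
ROH_CLASS_BREAKS_MBP <- c(1, 2, 4, 8, 16, Inf)

#' ROH calling parameters
#'
#' Defaults encode the consecutive-homozygote rule used throughout:
#' at least 25 homozygous markers, at least 1000 kbp span, no heterozygotes,
#' at most five unread SNPs per segment.
#'
#' @param min_snp minimum homozygous markers per segment (default 25).
#' @param min_length_bp minimum span in bp (default 1e6).
#' @param max_het maximum heterozygous calls allowed inside a segment
#'   (default 0).
#' @param max_missing maximum missing calls allowed inside a segment
#'   (default 5).
#' @return a list of class `roh_params`.
#' @export
roh_params <- function(min_snp = 25L, min_length_bp = 1000000L,
                       max_het = 0L, max_missing = 5L) {
  stopifnot(min_snp >= 0, min_length_bp > 0, max_het >= 0, max_missing >= 0)
  structure(list(min_snp = as.integer(min_snp),
                 min_length_bp = as.numeric(min_length_bp),
                 max_het = as.integer(max_het),
                 max_missing = as.integer(max_missing)),
            class = "roh_params")
}

#' Call ROH on one sample / one chromosome
#'
#' @param dosage integer dosage vector (0/1/2/NA) for one sample along one
#'   chromosome.
#' @param pos strictly increasing base-pair positions.
#' @param params a [roh_params()].
#' @return data.frame with columns `start_bp`, `end_bp`, `start_idx`,
#'   `end_idx`, `n_hom`, `n_het`, `n_missing`, `length_bp` (may have zero
#'   rows).
#' @export
call_roh_sample <- function(dosage, pos, params = roh_params()) {
  if (length(dosage) != length(pos)) stop("dosage and pos lengths differ")
  if (is.unsorted(pos, strictly = TRUE)) stop("positions must be strictly increasing")
  n <- length(dosage)
  empty <- data.frame(start_bp = integer(0), end_bp = integer(0),
                      start_idx = integer(0), end_idx = integer(0),
                      n_hom = integer(0), n_het = integer(0),
                      n_missing = integer(0), length_bp = numeric(0))
  if (n == 0L) return(empty)
  hom <- !is.na(dosage) & dosage != 1L
  het <- !is.na(dosage) & dosage == 1L
  mis <- is.na(dosage)
  hom_idx <- which(hom)
  if (!length(hom_idx)) return(empty)
  het_idx <- which(het)
  mis_idx <- which(mis)
  cum_hom <- cumsum(hom)
  cum_het <- cumsum(het)
  cum_mis <- cumsum(mis)
  # prev_hom[x]: largest homozygous index <= x (0 if none)
  prev_hom <- cummax(ifelse(hom, seq_len(n), 0L))

  out <- vector("list", 16L); n_out <- 0L
  ptr <- 1L
  while (ptr <= length(hom_idx)) {
    i <- hom_idx[ptr]
    # budget limits: index before the (max+1)-th het / missing at or after i
    kh <- cum_het[i] + params$max_het + 1L
    km <- cum_mis[i] + params$max_missing + 1L
    lim <- min(if (kh <= length(het_idx)) het_idx[kh] - 1L else n,
               if (km <= length(mis_idx)) mis_idx[km] - 1L else n)
    j <- prev_hom[lim]  # >= i because i <= lim and i is homozygous
    n_hom <- cum_hom[j] - cum_hom[i] + 1L
    span <- pos[j] - pos[i] + 1
    if (n_hom >= params$min_snp && span >= params$min_length_bp) {
      n_out <- n_out + 1L
      if (n_out > length(out)) out <- c(out, vector("list", length(out)))
      out[[n_out]] <- c(i, j, n_hom,
                        cum_het[j] - cum_het[i],
                        cum_mis[j] - cum_mis[i])
      # resume after the emitted run (non-overlap)
      ptr <- findInterval(j, hom_idx) + 1L
    } else {
      ptr <- ptr + 1L
    }
  }
  if (n_out == 0L) return(empty)
  rec <- do.call(rbind, out[seq_len(n_out)])
  data.frame(start_bp = pos[rec[, 1]], end_bp = pos[rec[, 2]],
             start_idx = rec[, 1], end_idx = rec[, 2],
             n_hom = rec[, 3], n_het = rec[, 4], n_missing = rec[, 5],
             length_bp = pos[rec[, 2]] - pos[rec[, 1]] + 1)
}

#' Call ROH for all samples on all autosomes
#'
#' Expects a ROH-profile dataset (autosomes only); the presence of X
#' markers is an error. Output rows are ordered by (sample, chromosome,
#' start).
#'
#' @param geno dosage matrix.
#' @param map marker map.
#' @param params a [roh_params()].
#' @return data.frame of segments with columns `sample_id`, `chrom`,
#'   `start_bp`, `end_bp`, `n_hom`, `n_missing`, `length_bp`,
#'   `length_class`.
#' @export
call_roh_all <- function(geno, map, params = roh_params()) {
  validate_genotypes(geno, map)
  if (any(map$chrom == "X")) {
    stop("X-chromosome markers present; ROH calling expects autosomes only")
  }
  samples <- rownames(geno) %||% as.character(seq_len(nrow(geno)))
  chroms <- unique(map$chrom)
  res <- list()
  for (ch in chroms) {
    cols <- which(map$chrom == ch)
    pos <- map$pos_bp[cols]
    for (s in seq_len(nrow(geno))) {
      seg <- call_roh_sample(geno[s, cols], pos, params)
      if (nrow(seg)) {
        res[[length(res) + 1L]] <- data.frame(
          sample_id = samples[s], chrom = ch,
          start_bp = seg$start_bp, end_bp = seg$end_bp,
          n_hom = seg$n_hom, n_missing = seg$n_missing,
          length_bp = seg$length_bp,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) {
    segs <- data.frame(sample_id = character(0), chrom = character(0),
                       start_bp = integer(0), end_bp = integer(0),
                       n_hom = integer(0), n_missing = integer(0),
                       length_bp = numeric(0))
  } else {
    segs <- do.call(rbind, res)
  }
  segs <- segs[order(match(segs$sample_id, samples),
                     chrom_rank(segs$chrom), segs$start_bp), , drop = FALSE]
  rownames(segs) <- NULL
  segs$length_class <- if (nrow(segs)) classify_roh_length(segs$length_bp)
  else character(0)
  segs
}

#' Classify a ROH length into the five reporting classes
#'
#' Half-open bins \[1,2), \[2,4), \[4,8), \[8,16), \[16,Inf) Mbp labelled
#' `"1-2"`, `"2-4"`, `"4-8"`, `"8-16"`, `">16"`.
#'
#' @param length_bp segment length(s) in bp; must be >= 1 Mbp.
#' @return character vector of class labels.
#' @export
classify_roh_length <- function(length_bp) {
  if (any(length_bp < 1e6)) stop("ROH length below 1 Mbp cannot be classified")
  ROH_CLASS_LABELS[findInterval(length_bp / 1e6, ROH_CLASS_BREAKS_MBP)]
}

#' Grand mean ROH length
#'
#' Total ROH length divided by total ROH count — the population mean
#' segment length, in the units of `total_length`.
#'
#' @param total_length summed segment length (any consistent unit).
#' @param total_count summed segment count.
#' @return the ratio.
#' @export
roh_grand_mean_length <- function(total_length, total_count) {
  if (total_count <= 0) stop("total_count must be positive")
  total_length / total_count
}

#' Summarize called ROH segments
#'
#' Per-animal counts and total lengths overall and per length class, plus
#' population statistics. Per-class mean/SD/median/min/max are computed over
#' animals possessing at least one ROH of that class; the share of animals
#' without any segment of a class is reported separately.
#'
#' @param segments data.frame from [call_roh_all()].
#' @param samples character vector of all sample IDs in the analysis
#'   (animals without any ROH still count in per-animal averages).
#' @return a list of class `roh_summary` with elements `per_animal`
#'   (data.frame), `class_stats` (data.frame), `n_segments`,
#'   `mean_per_animal`, `grand_mean_length_mbp`, `total_length_mbp`,
#'   `mean_total_length_mbp`.
#' @export
summarize_roh <- function(segments, samples) {
  if (nrow(segments) == 0L) {
    warning("no ROH segments; summary is all zeros")
  }
  cls <- factor(segments$length_class, levels = ROH_CLASS_LABELS)
  sid <- factor(segments$sample_id, levels = samples)
  cnt <- table(sid, cls)
  len <- tapply(segments$length_bp / 1e6, list(sid, cls), sum, default = 0)
  len[is.na(len)] <- 0
  per_animal <- data.frame(sample_id = samples,
                           n_roh = as.integer(rowSums(cnt)),
                           total_mbp = rowSums(len))
  for (cl in ROH_CLASS_LABELS) {
    per_animal[[paste0("n_", cl)]] <- as.integer(cnt[, cl])
    per_animal[[paste0("mbp_", cl)]] <- len[, cl]
  }
  rownames(per_animal) <- NULL

  stat_row <- function(x) c(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else NA_real_,
                            median = stats::median(x), min = min(x), max = max(x))
  class_stats <- do.call(rbind, lapply(ROH_CLASS_LABELS, function(cl) {
    has <- cnt[, cl] > 0
    if (!any(has)) {
      return(data.frame(class = cl, n_animals = 0L, pct_without = 100,
                        t(stat_row(NA_real_) * NA_real_),
                        t(stats::setNames(stat_row(NA_real_) * NA_real_,
                                          paste0("len_", names(stat_row(0)))))))
    }
    cs <- stat_row(as.numeric(cnt[has, cl]))
    ls <- stat_row(len[has, cl])
    data.frame(class = cl, n_animals = sum(has),
               pct_without = 100 * mean(!has),
               t(cs), t(stats::setNames(ls, paste0("len_", names(ls)))))
  }))
  rownames(class_stats) <- NULL

  total_len <- sum(segments$length_bp) / 1e6
  n_seg <- nrow(segments)
  structure(list(per_animal = per_animal,
                 class_stats = class_stats,
                 n_segments = n_seg,
                 mean_per_animal = n_seg / length(samples),
                 total_length_mbp = total_len,
                 mean_total_length_mbp = total_len / length(samples),
                 grand_mean_length_mbp = if (n_seg > 0)
                   roh_grand_mean_length(total_len, n_seg) else 0),
            class = "roh_summary")
}

#' Format a share of animals as an integer percentage
#'
#' @param k count of animals with the property.
#' @param n total animals.
#' @return integer percentage, rounded half away from zero at .5.
#' @export
pct_of_animals <- function(k, n) {
  if (n <= 0) stop("n must be positive")
  as.integer(floor(100 * k / n + 0.5))
}

#' Write ROH segments as TSV and BED
#'
#' The TSV is 1-based inclusive; the BED is 0-based half-open.
#'
#' @param segments data.frame from [call_roh_all()].
#' @param prefix output path prefix (`.roh.tsv`, `.roh.bed` appended).
#' @return invisibly, the two paths.
#' @export
write_roh <- function(segments, prefix) {
  tsv <- paste0(prefix, ".roh.tsv")
  bed <- paste0(prefix, ".roh.bed")
  utils::write.table(segments, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(segments$chrom, segments$start_bp - 1L, segments$end_bp,
               paste0(segments$sample_id, ":", segments$length_class)),
    bed, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(c(tsv = tsv, bed = bed))
}
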