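# Genomic inbreeding from ROH: F_ROH overall and per length class.

#' Bos taurus autosome length constant (bp)
#'
#' Fixed denominator for F_ROH on real bovine data: 2,512,082,506 bp.
#' Simulated genomes pass their own autosome length instead.
#' @export
BTA_AUTOSOME_BP <- 2512082506

#' @keywords internal
check_no_overlap <- function(segments) {
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, , drop = FALSE]
    s <- s[order(s$start_bp), , drop = FALSE]
    if (nrow(s) > 1 && any(s$start_bp[-1] <= s$end_bp[-nrow(s)])) {
      stop("overlapping ROH segments on chromosome ", ch,
           " (upstream caller bug)")
    }
  }
  invisible(TRUE)
}

#' Genomic inbreeding coefficient F_ROH for one animal
#'
#' The proportion of the autosomal genome covered by the animal's ROH:
#' the sum of segment lengths over the autosome length.
#'
#' @param segments data.frame of one animal's segments (needs `chrom`,
#'   `start_bp`, `end_bp`, `length_bp`); must be non-overlapping per
#'   chromosome.
#' @param autosome_length_bp denominator (default [BTA_AUTOSOME_BP]).
#' @return F_ROH in `[0, 1]`.
#' @export
froh <- function(segments, autosome_length_bp = BTA_AUTOSOME_BP) {
  if (nrow(segments) == 0L) return(0)
  check_no_overlap(segments)
  sum(segments$length_bp) / autosome_length_bp
}

#' Per-length-class F_ROH for one animal
#'
#' Class-partitioned sums over the same autosome denominator; the five
#' values add up to [froh()] exactly.
#'
#' @inheritParams froh
#' @return named numeric vector over the classes `1-2`, `2-4`, `4-8`,
#'   `8-16`, `>16`.
#' @export
froh_by_class <- function(segments, autosome_length_bp = BTA_AUTOSOME_BP) {
  out <- stats::setNames(numeric(length(ROH_CLASS_LABELS)), ROH_CLASS_LABELS)
  if (nrow(segments) == 0L) return(out)
  check_no_overlap(segments)
  cls <- if ("length_class" %in% names(segments)) segments$length_class
  else classify_roh_length(segments$length_bp)
  s <- tapply(segments$length_bp, factor(cls, levels = ROH_CLASS_LABELS),
              sum, default = 0)
  out[] <- as.numeric(s) / autosome_length_bp
  out
}

#' F_ROH for every animal in a segment table
#'
#' @param segments data.frame from [call_roh_all()].
#' @param samples all sample IDs (animals without ROH get F_ROH 0).
#' @param autosome_length_bp denominator (default [BTA_AUTOSOME_BP]).
#' @return data.frame with `sample_id`, `f_roh_total` and one column per
#'   length class (`f_roh_1-2`, ..., `f_roh_>16`).
#' @export
froh_all <- function(segments, samples, autosome_length_bp = BTA_AUTOSOME_BP) {
  rows <- lapply(samples, function(s) {
    seg <- segments[segments$sample_id == s, , drop = FALSE]
    by_cls <- froh_by_class(seg, autosome_length_bp)
    c(f_roh_total = sum(by_cls), by_cls)
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("f_roh_total", paste0("f_roh_", ROH_CLASS_LABELS))
  cbind(data.frame(sample_id = samples, stringsAsFactors = FALSE), out)
}

#' Population distribution of F_ROH
#'
#' Mean/SD/median/min/max of total F_ROH and of each per-class F_ROH over
#' all animals (zeros included), in boxplot-ready long form. With a single
#' animal the SD is reported as `NA`.
#'
#' @param results data.frame from [froh_all()].
#' @return data.frame with one row per component (`total` plus the five
#'   classes) and columns `mean`, `sd`, `median`, `min`, `max`.
#' @export
froh_population_summary <- function(results) {
  stopifnot(nrow(results) >= 1)
  cols <- c("f_roh_total", paste0("f_roh_", ROH_CLASS_LABELS))
  out <- do.call(rbind, lapply(cols, function(cn) {
    x <- results[[cn]]
    data.frame(component = sub("^f_roh_", "", cn),
               mean = mean(x),
               sd = if (length(x) > 1) stats::sd(x) else NA_real_,
               median = stats::median(x), min = min(x), max = max(x))
  }))
  out$component[out$component == "total"] <- "total"
  rownames(out) <- NULL
  out
}
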