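# ROH islands: per-marker SNP-in-ROH frequency and threshold scan.

#' Per-marker SNP-in-ROH frequency
#'
#' For each marker, the percentage of animals whose ROH covers its
#' position. Each animal is counted at most once per marker even if its
#' segment table contains overlapping runs (they are merged per animal
#' first).
#'
#' @param segments data.frame of ROH segments (`sample_id`, `chrom`,
#'   `start_bp`, `end_bp`).
#' @param map marker map the segments were called on.
#' @param n_samples total number of animals in the population.
#' @return data.frame with `marker_id`, `chrom`, `pos_bp`, `n_in_roh`,
#'   `pct_in_roh`.
#' @export
snp_in_roh_frequency <- function(segments, map, n_samples) {
  if (n_samples <= 0) stop("n_samples must be positive")
  cnt <- integer(nrow(map))
  for (ch in unique(map$chrom)) {
    rows <- which(map$chrom == ch)
    seg <- segments[segments$chrom == ch, , drop = FALSE]
    if (!nrow(seg)) next
    # merge per animal so overlapping runs count once
    merged <- do.call(rbind, lapply(split(seg, seg$sample_id), function(s) {
      s <- s[order(s$start_bp), , drop = FALSE]
      st <- s$start_bp; en <- s$end_bp
      keep_st <- st[1]; keep_en <- en[1]
      if (nrow(s) > 1) for (i in 2:nrow(s)) {
        k <- length(keep_en)
        if (st[i] <= keep_en[k]) keep_en[k] <- max(keep_en[k], en[i])
        else { keep_st <- c(keep_st, st[i]); keep_en <- c(keep_en, en[i]) }
      }
      cbind(keep_st, keep_en)
    }))
    starts <- sort(merged[, 1])
    ends <- sort(merged[, 2])
    pos <- map$pos_bp[rows]
    # intervals covering pos = #(start <= pos) - #(end < pos)
    cnt[rows] <- findInterval(pos, starts) - findInterval(pos - 1L, ends)
  }
  data.frame(marker_id = map$marker_id, chrom = map$chrom,
             pos_bp = map$pos_bp, n_in_roh = cnt,
             pct_in_roh = 100 * cnt / n_samples,
             stringsAsFactors = FALSE)
}

#' Detect ROH islands
#'
#' Maximal runs of consecutive markers whose SNP-in-ROH frequency is at
#' least `threshold_pct` (inclusive), per chromosome, with at least
#' `min_markers` members. Island coordinates span the first to the last
#' member marker.
#'
#' @param track data.frame from [snp_in_roh_frequency()].
#' @param threshold_pct inclusive percentage threshold (default 30).
#' @param min_markers minimum member markers per island (default 1).
#' @return data.frame with `chrom`, `start_bp`, `end_bp`, `n_markers`,
#'   `peak_pct`, `peak_marker_ids` (comma-separated).
#' @export
detect_islands <- function(track, threshold_pct = 30, min_markers = 1L) {
  empty <- data.frame(chrom = character(0), start_bp = integer(0),
                      end_bp = integer(0), n_markers = integer(0),
                      peak_pct = numeric(0), peak_marker_ids = character(0),
                      stringsAsFactors = FALSE)
  res <- list()
  for (ch in unique(track$chrom)) {
    tr <- track[track$chrom == ch, , drop = FALSE]
    tr <- tr[order(tr$pos_bp), , drop = FALSE]
    above <- tr$pct_in_roh >= threshold_pct
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_markers)) {
      idx <- starts[k]:ends[k]
      peak <- max(tr$pct_in_roh[idx])
      res[[length(res) + 1L]] <- data.frame(
        chrom = ch, start_bp = tr$pos_bp[idx[1]],
        end_bp = tr$pos_bp[idx[length(idx)]],
        n_markers = length(idx), peak_pct = peak,
        peak_marker_ids = paste(
          tr$marker_id[idx][tr$pct_in_roh[idx] == peak], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out <- out[order(chrom_rank(out$chrom), out$start_bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Manhattan-style island report
#'
#' One row per island with peak statistics; the full per-marker track is
#' attached as attribute `"track"` for plotting.
#'
#' @param islands data.frame from [detect_islands()].
#' @param track data.frame from [snp_in_roh_frequency()].
#' @return the islands data.frame with a `track` attribute.
#' @export
island_report <- function(islands, track) {
  out <- islands
  attr(out, "track") <- track[order(chrom_rank(track$chrom), track$pos_bp), ]
  out
}

#' Write island track and calls
#'
#' @param islands data.frame from [detect_islands()].
#' @param track data.frame from [snp_in_roh_frequency()].
#' @param prefix output path prefix.
#' @return invisibly, the written paths (track TSV, islands TSV, BED).
#' @export
write_islands <- function(islands, track, prefix) {
  p1 <- paste0(prefix, ".roh_freq.tsv")
  p2 <- paste0(prefix, ".islands.tsv")
  p3 <- paste0(prefix, ".islands.bed")
  utils::write.table(track, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(islands, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(islands$chrom, islands$start_bp - 1L, islands$end_bp,
               sprintf("peak_%.1f", islands$peak_pct)),
    p3, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(c(track = p1, islands = p2, bed = p3))
}
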