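#' Per-SNP log2 coverage-ratio track
#'
#' Computes, at every SNP position shared by tumor and germline, the
#' log2 of the ratio of normalized read coverages
#' (`(tumor_i / tumor_total) / (germline_i / germline_total)`), then
#' recenters the track to zero by subtracting the genome-wide median
#' (or mean). Positions with zero coverage in either sample are dropped
#' and counted in the `n_dropped` attribute.
#'
#' @param tumor,germline [snp_table()]s matched on (chrom, pos).
#' @param center `"median"` (robust to high CNV burden, the default) or
#'   `"mean"`.
#' @return data frame of class `cnv_track`, sorted by chromosome then
#'   position, with columns `chrom`, `pos`, `raw_log2`, `smoothed_log2`
#'   (`NA` until [moving_average()] is applied).
#' @export
log2_ratio_track <- function(tumor, germline, center = c("median", "mean")) {
  center <- match.arg(center)
  key_t <- paste(tumor$chrom, tumor$pos)
  key_g <- paste(germline$chrom, germline$pos)
  common <- intersect(key_t, key_g)
  ti <- match(common, key_t); gi <- match(common, key_g)
  t_cov <- tumor$ref_count[ti] + tumor$alt_count[ti]
  g_cov <- germline$ref_count[gi] + germline$alt_count[gi]
  ok <- t_cov > 0 & g_cov > 0
  n_dropped <- sum(!ok)
  if (!any(ok)) {
    warning("no common positions with coverage in both samples")
    out <- data.frame(chrom = character(), pos = numeric(),
                      raw_log2 = numeric(), smoothed_log2 = numeric())
    class(out) <- c("cnv_track", "data.frame")
    attr(out, "n_dropped") <- n_dropped
    return(out)
  }
  t_cov <- t_cov[ok]; g_cov <- g_cov[ok]
  raw <- log2((t_cov / sum(t_cov)) / (g_cov / sum(g_cov)))
  shift <- if (center == "median") median(raw) else mean(raw)
  out <- data.frame(chrom = tumor$chrom[ti][ok], pos = tumor$pos[ti][ok],
                    raw_log2 = raw - shift, smoothed_log2 = NA_real_,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cnv_track", "data.frame")
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Moving-average smoothing over adjacent SNPs
#'
#' Fills `smoothed_log2` with the mean of `raw_log2` over a window of
#' `window` adjacent SNPs within each chromosome. The window is
#' centered (for even `window`, one extra SNP on the right); near
#' chromosome ends the available, shorter window is used. A trailing
#' window is available via `align = "right"`.
#'
#' @param track a `cnv_track` from [log2_ratio_track()].
#' @param window number of adjacent SNPs (>= 1).
#' @param align `"center"` (default) or `"right"` (trailing).
#' @return the track with `smoothed_log2` filled in.
#' @export
moving_average <- function(track, window = 10, align = c("center", "right")) {
  align <- match.arg(align)
  if (!is.numeric(window) || length(window) != 1 || window < 1 ||
      window != floor(window)) {
    stop("window must be a whole number >= 1", call. = FALSE)
  }
  left <- if (align == "center") floor((window - 1) / 2) else window - 1
  right <- window - 1 - left
  for (chr in unique(track$chrom)) {
    idx <- which(track$chrom == chr)
    x <- track$raw_log2[idx]
    n <- length(x)
    cs <- cumsum(c(0, x))
    lo <- pmax(seq_len(n) - left, 1)
    hi <- pmin(seq_len(n) + right, n)
    track$smoothed_log2[idx] <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  track
}

#' Threshold-based CNV segment calls
#'
#' Maximal runs of at least `min_snps` consecutive SNPs whose smoothed
#' log2 ratio lies below `del_threshold` (deletion) or above
#' `amp_threshold` (amplification) become segments; same-call runs
#' separated by a gap of fewer than 2 SNPs are merged first. Runs never
#' cross chromosome boundaries. The thresholds are package defaults,
#' not published values.
#'
#' @param track a smoothed `cnv_track` (run [moving_average()] first).
#' @param del_threshold,amp_threshold log2-ratio cutoffs
#'   (`del_threshold < amp_threshold` required).
#' @param min_snps minimum run length.
#' @return data frame of class `cnv_segments`: `chrom`, `start`, `end`
#'   (0-based half-open, spanning first to last SNP of the run),
#'   `call` (`deletion`/`amplification`), `mean_smoothed_log2`,
#'   `n_snps`.
#' @export
call_segments <- function(track, del_threshold = -0.3,
                          amp_threshold = 0.3, min_snps = 10) {
  if (del_threshold >= amp_threshold) {
    stop("del_threshold must be below amp_threshold", call. = FALSE)
  }
  if (any(is.na(track$smoothed_log2)) && nrow(track) > 0) {
    stop("smoothed values missing: run moving_average() first",
         call. = FALSE)
  }
  segs <- list()
  for (chr in unique(track$chrom)) {
    t <- track[track$chrom == chr, , drop = FALSE]
    for (call in c("deletion", "amplification")) {
      hit <- if (call == "deletion") t$smoothed_log2 < del_threshold
             else t$smoothed_log2 > amp_threshold
      runs <- find_runs(hit, max_gap = 1)
      for (r in runs) {
        if (sum(hit[r[1]:r[2]]) < min_snps) next
        n_in <- r[2] - r[1] + 1
        if (n_in < min_snps) next
        segs[[length(segs) + 1]] <- data.frame(
          chrom = chr,
          start = t$pos[r[1]] - 1, end = t$pos[r[2]],
          call = call,
          mean_smoothed_log2 = mean(t$smoothed_log2[r[1]:r[2]]),
          n_snps = n_in,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(segs)) do.call(rbind, segs) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               call = character(), mean_smoothed_log2 = numeric(),
               n_snps = integer(), stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cnv_segments", "data.frame")
  out
}

# maximal runs of TRUE, merging runs separated by <= max_gap FALSEs
find_runs <- function(hit, max_gap = 0) {
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  true_i <- which(r$values)
  if (!length(true_i)) return(list())
  runs <- list(c(starts[true_i[1]], ends[true_i[1]]))
  for (i in true_i[-1]) {
    last <- runs[[length(runs)]]
    gap <- starts[i] - last[2] - 1
    if (gap <= max_gap) {
      runs[[length(runs)]][2] <- ends[i]
    } else {
      runs[[length(runs) + 1]] <- c(starts[i], ends[i])
    }
  }
  runs
}

#' Annotate gene loci with overlapping CNV calls
#'
#' @param segments a `cnv_segments` table from [call_segments()].
#' @param loci a [region_set()] of gene loci (labels required), e.g.
#'   `load_fixture("akap_cnv")$loci`.
#' @return data frame: `locus`, `call` (`deletion`, `amplification`,
#'   `neutral`, or `conflict` when both overlap), `calls` listing every
#'   overlapping call.
#' @export
annotate_loci <- function(segments, loci) {
  stopifnot(inherits(loci, "region_set"))
  res <- lapply(seq_len(nrow(loci)), function(i) {
    ov <- segments$chrom == loci$chrom[i] &
      segments$start < loci$end[i] & loci$start[i] < segments$end
    calls <- unique(segments$call[ov])
    call <- if (length(calls) == 0) "neutral"
            else if (length(calls) == 1) calls
            else "conflict"
    data.frame(locus = loci$label[i], call = call,
               calls = paste(sort(calls), collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
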