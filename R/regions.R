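#' Genomic region sets
#'
#' A `region_set` is a light-weight container for 0-based half-open
#' genomic intervals (BED convention), used for LOH blocks, CNV segments
#' and gene loci. Intervals are validated (`start < end`) and stored
#' sorted by chromosome then start.
#'
#' @param chrom character vector of chromosome labels.
#' @param start,end integer vectors; 0-based half-open coordinates.
#' @param label optional character vector of interval names.
#' @return A data frame of class `region_set` with columns `chrom`,
#'   `start`, `end`, `label`.
#' @examples
#' region_set("chr6", 151560000, 151750000, "AKAP12")
#' @export
region_set <- function(chrom = character(), start = integer(),
                       end = integer(), label = NULL) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- length(chrom)
  if (length(start) != n || length(end) != n) {
    stop("chrom, start and end must have equal length", call. = FALSE)
  }
  if (is.null(label)) label <- rep(NA_character_, n)
  if (any(!is.finite(start)) || any(!is.finite(end)) || any(start < 0)) {
    stop("region coordinates must be finite and non-negative", call. = FALSE)
  }
  if (any(start >= end)) {
    stop("region_set requires start < end for every interval", call. = FALSE)
  }
  df <- data.frame(chrom = chrom, start = start, end = end,
                   label = as.character(label), stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("region_set", "data.frame")
  df
}

#' Read a BED file into a region_set
#'
#' Uses \pkg{rtracklayer} to parse the BED file, then converts back to
#' the 0-based half-open coordinates that BED itself uses.
#'
#' @param path path to a BED file (3+ columns, no header).
#' @return a [region_set()].
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  df <- as.data.frame(gr)
  label <- if ("name" %in% names(df)) as.character(df$name) else NULL
  region_set(as.character(df$seqnames), df$start - 1L, df$end, label)
}

#' Write a region_set as a BED file
#'
#' @param regions a [region_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  stopifnot(inherits(regions, "region_set"))
  df <- regions
  df$label[is.na(df$label)] <- "."
  # coordinates already BED-convention; plain formatting, no header
  write.table(df[, c("chrom", "start", "end", "label")], path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Membership of 1-based positions in a region_set
#'
#' @param chrom,pos vectors of chromosome labels and 1-based positions.
#' @param regions a [region_set()] (may have zero rows).
#' @return logical vector: does each position fall inside any interval?
#' @export
in_regions <- function(chrom, pos, regions) {
  if (is.null(regions) || nrow(regions) == 0) {
    return(rep(FALSE, length(pos)))
  }
  hit <- rep(FALSE, length(pos))
  p0 <- pos - 1   # 0-based
  for (i in seq_len(nrow(regions))) {
    hit <- hit | (chrom == regions$chrom[i] &
                    p0 >= regions$start[i] & p0 < regions$end[i])
  }
  hit
}

#' Index of the covering region (first match) for 1-based positions
#' @noRd
region_index <- function(chrom, pos, regions) {
  idx <- rep(NA_integer_, length(pos))
  if (is.null(regions) || nrow(regions) == 0) return(idx)
  p0 <- pos - 1
  for (i in rev(seq_len(nrow(regions)))) {
    m <- chrom == regions$chrom[i] & p0 >= regions$start[i] & p0 < regions$end[i]
    idx[m] <- i
  }
  idx
}

#' Do any intervals of two region sets overlap? (pairwise matrix helper)
#' @noRd
regions_overlap_any <- function(a_chrom, a_start, a_end,
                                b_chrom, b_start, b_end) {
  a_chrom == b_chrom & a_start < b_end & b_start < a_end
}

#' Validate that a region_set has no overlapping intervals
#' @noRd
assert_disjoint <- function(regions, what = "regions") {
  if (nrow(regions) < 2) return(invisible(TRUE))
  for (chr in unique(regions$chrom)) {
    r <- regions[regions$chrom == chr, , drop = FALSE]
    if (nrow(r) > 1 && any(r$start[-1] < r$end[-nrow(r)])) {
      stop(sprintf("overlapping intervals in %s on %s", what, chr),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}
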