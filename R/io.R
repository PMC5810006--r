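#' Per-position SNP observation tables
#'
#' A SNP observation table holds per-position reference/alternate read
#' counts for one sample: the atom of the CNV and LOH computations.
#' Columns: `chrom`, `pos` (1-based), `ref_count`, `alt_count`,
#' `sample_id`.
#'
#' @param chrom,pos,ref_count,alt_count,sample_id column vectors.
#' @return data frame of class `snp_table`.
#' @export
snp_table <- function(chrom, pos, ref_count, alt_count, sample_id) {
  df <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                   ref_count = as.numeric(ref_count),
                   alt_count = as.numeric(alt_count),
                   sample_id = as.character(sample_id),
                   stringsAsFactors = FALSE)
  validate_snp_table(df)
  class(df) <- c("snp_table", "data.frame")
  df
}

validate_snp_table <- function(df, path = NULL) {
  req <- c("chrom", "pos", "ref_count", "alt_count", "sample_id")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop(sprintf("SNP table%s is missing required column(s): %s",
                 if (is.null(path)) "" else paste0(" '", path, "'"),
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  bad <- which(!is.finite(df$ref_count) | !is.finite(df$alt_count) |
                 df$ref_count < 0 | df$alt_count < 0)
  if (length(bad)) {
    stop(sprintf("negative or non-numeric read counts at row(s): %s",
                 paste(head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Read a SNP observation table from TSV
#'
#' Expects a tab-separated file with header columns `chrom`, `pos`,
#' `ref_count`, `alt_count`, `sample_id`. Malformed rows (negative
#' counts) are reported with their row numbers.
#'
#' @param path file path.
#' @return a [snp_table()].
#' @export
read_snp_table <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  validate_snp_table(df, path)
  snp_table(df$chrom, df$pos, df$ref_count, df$alt_count, df$sample_id)
}

#' @rdname read_snp_table
#' @param x a [snp_table()] to write.
#' @export
write_snp_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

VARIANT_COLS <- c("chrom", "pos", "ref", "alt",
                  "germline_ref", "germline_alt", "tumor_ref", "tumor_alt",
                  "tumor_alt_fwd", "tumor_alt_rev",
                  "gene", "consequence", "sample_id", "compartment")

#' Candidate somatic variant tables
#'
#' One row per candidate variant with paired germline/tumor read counts,
#' strand-split alternate counts (may be `NA` when the caller did not
#' report them), gene annotation and compartment label
#' (`primary`, `metastasis`, `axillary` or `germline`).
#'
#' @param df data frame carrying the columns listed in the details.
#' @return data frame of class `variant_table`.
#' @export
variant_table <- function(df) {
  for (col in VARIANT_COLS) {
    if (!col %in% names(df)) {
      if (col %in% c("tumor_alt_fwd", "tumor_alt_rev")) {
        df[[col]] <- NA_real_
      } else if (col %in% c("gene", "consequence")) {
        df[[col]] <- ""
      } else {
        stop(sprintf("variant table is missing required column: %s", col),
             call. = FALSE)
      }
    }
  }
  num <- c("pos", "germline_ref", "germline_alt", "tumor_ref", "tumor_alt",
           "tumor_alt_fwd", "tumor_alt_rev")
  for (col in num) df[[col]] <- as.numeric(df[[col]])
  chr <- c("chrom", "ref", "alt", "gene", "consequence", "sample_id",
           "compartment")
  for (col in chr) df[[col]] <- as.character(df[[col]])
  counts <- c("germline_ref", "germline_alt", "tumor_ref", "tumor_alt")
  bad <- which(Reduce(`|`, lapply(df[counts], function(v)
    !is.finite(v) | v < 0)))
  if (length(bad)) {
    stop(sprintf("negative or non-numeric counts at row(s): %s",
                 paste(head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  strands <- is.finite(df$tumor_alt_fwd) & is.finite(df$tumor_alt_rev)
  off <- strands & (df$tumor_alt_fwd + df$tumor_alt_rev != df$tumor_alt)
  if (any(off)) {
    stop(sprintf("strand counts do not sum to tumor_alt at row(s): %s",
                 paste(head(which(off), 5), collapse = ", ")), call. = FALSE)
  }
  df <- df[, VARIANT_COLS]
  class(df) <- c("variant_table", "data.frame")
  df
}

#' Read a candidate variant table
#'
#' Two dialects are supported. `varscan_like` is a tab-separated file
#' with the columns of a joined VarScan-somatic-style report
#' (`chrom`, `pos`, `ref`, `alt`, `germline_ref`, `germline_alt`,
#' `tumor_ref`, `tumor_alt`, `tumor_alt_fwd`, `tumor_alt_rev`, `gene`,
#' `consequence`, `sample_id`, `compartment`); missing strand columns
#' are tolerated and marked `NA`. `vcf` reads a paired tumor/normal VCF
#' through \pkg{VariantAnnotation}, mapping per-sample `AD` allele
#' depths onto germline/tumor ref/alt counts; multi-allelic rows are
#' split into biallelic records with a warning.
#'
#' @param path file path.
#' @param dialect `"varscan_like"` or `"vcf"`.
#' @param germline_sample,tumor_sample sample names in the VCF; default
#'   to the first and second genotype column.
#' @param sample_id,compartment labels attached to VCF-derived records.
#' @return a [variant_table()].
#' @export
read_variant_table <- function(path, dialect = c("varscan_like", "vcf"),
                               germline_sample = NULL, tumor_sample = NULL,
                               sample_id = "sample", compartment = "primary") {
  dialect <- match.arg(dialect)
  if (dialect == "varscan_like") {
    df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                     check.names = FALSE)
    return(variant_table(df))
  }
  read_variant_vcf(path, germline_sample, tumor_sample, sample_id,
                   compartment)
}

read_variant_vcf <- function(path, germline_sample, tumor_sample,
                             sample_id, compartment) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("the 'vcf' dialect requires the VariantAnnotation package",
         call. = FALSE)
  }
  vcf <- VariantAnnotation::readVcf(path)
  if (any(lengths(VariantAnnotation::alt(vcf)) > 1)) {
    warning("multi-allelic VCF rows split into biallelic records")
  }
  vcf <- VariantAnnotation::expand(vcf)   # no-op for biallelic rows
  smp <- colnames(vcf)
  if (length(smp) < 2) stop("paired VCF needs two genotype columns",
                            call. = FALSE)
  if (is.null(germline_sample)) germline_sample <- smp[1]
  if (is.null(tumor_sample)) tumor_sample <- smp[2]
  ad <- VariantAnnotation::geno(vcf)$AD
  if (is.null(ad)) stop("VCF has no AD (allele depth) genotype field",
                        call. = FALSE)
  rr <- as.data.frame(SummarizedExperiment::rowRanges(vcf))
  # AD arrives as an n x sample x allele array when all lengths agree,
  # or as a list-matrix otherwise
  get_ad <- function(sample, k) {
    if (is.array(ad) && length(dim(ad)) == 3) {
      v <- ad[, sample, k]
      return(ifelse(is.na(v), 0, as.numeric(v)))
    }
    vapply(seq_len(nrow(vcf)), function(i) {
      v <- ad[[i, sample]]
      if (length(v) >= k && !is.na(v[k])) as.numeric(v[k]) else 0
    }, numeric(1))
  }
  df <- data.frame(
    chrom = as.character(rr$seqnames),
    pos = rr$start,
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = as.character(VariantAnnotation::alt(vcf)),
    germline_ref = get_ad(germline_sample, 1),
    germline_alt = get_ad(germline_sample, 2),
    tumor_ref = get_ad(tumor_sample, 1),
    tumor_alt = get_ad(tumor_sample, 2),
    tumor_alt_fwd = NA_real_, tumor_alt_rev = NA_real_,
    gene = "", consequence = "",
    sample_id = sample_id, compartment = compartment,
    stringsAsFactors = FALSE)
  variant_table(df)
}

#' @rdname read_variant_table
#' @param x a [variant_table()] to write.
#' @export
write_variant_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Germline and tumor variant allele fractions
#'
#' @param x a [variant_table()].
#' @return numeric vector of fractions; `NA` where the denominator is 0.
#' @export
tumor_vaf <- function(x) {
  tot <- x$tumor_ref + x$tumor_alt
  ifelse(tot > 0, x$tumor_alt / tot, NA_real_)
}

#' @rdname tumor_vaf
#' @export
germline_vaf <- function(x) {
  tot <- x$germline_ref + x$germline_alt
  ifelse(tot > 0, x$germline_alt / tot, NA_real_)
}

#' The 14 A-kinase anchoring protein (AKAP) gene symbols
#' @return character vector `AKAP1` ... `AKAP14`.
#' @export
akap_genes <- function() paste0("AKAP", 1:14)

#' Packaged mutation-table and CNV fixtures
#'
#' Small plain-text transcriptions of the published AKAP mutation and
#' copy-number tables shipped with the package:
#' \describe{
#'   \item{`cohort1_akap`}{9 nonsynonymous AKAP somatic mutations from
#'     the ten-patient discovery cohort, with primary and metastasis
#'     VAFs.}
#'   \item{`cohort2_akap`}{4 nonsynonymous AKAP mutations from the
#'     20-patient validation cohort, with VAFs across up to four
#'     lesions. Cells holding two VAFs from multiple blocks of one
#'     sample are stored as `;`-separated lists; summaries use the
#'     maximum.}
#'   \item{`akap_cnv`}{AKAP locus windows plus the unambiguous
#'     per-patient deletion/amplification calls of the discovery cohort
#'     and the validation-cohort counts restated in prose. Locus
#'     coordinates are approximate windows around the reported mutation
#'     positions / megabase locations.}
#' }
#' VAFs are stored as fractions in `[0, 1]` (a printed "5.2\%" becomes
#' 0.052); empty cells mean "not assayed" and are distinct from 0.
#'
#' @param name one of `"cohort1_akap"`, `"cohort2_akap"`, `"akap_cnv"`.
#' @return for the mutation tables, a data frame of class
#'   `mutation_table` with one row per mutation; for `akap_cnv`, a list
#'   with elements `loci` (a [region_set()]), `calls` (per-patient
#'   cohort-1 calls) and `cohort2_counts`.
#' @examples
#' nrow(load_fixture("cohort1_akap"))  # 9
#' @export
load_fixture <- function(name = c("cohort1_akap", "cohort2_akap",
                                  "akap_cnv")) {
  name <- match.arg(name)
  ext <- function(f) system.file("extdata", f, package = "pairedmet",
                                 mustWork = TRUE)
  if (name == "akap_cnv") {
    loci <- read_bed(ext("akap_loci.bed"))
    calls <- read.delim(ext("akap_cnv_calls.tsv"), sep = "\t",
                        stringsAsFactors = FALSE)
    c2 <- read.delim(ext("akap_cnv_cohort2_counts.tsv"), sep = "\t",
                     stringsAsFactors = FALSE)
    return(list(loci = loci, calls = calls, cohort2_counts = c2))
  }
  f <- if (name == "cohort1_akap") "cohort1_akap.tsv" else "cohort2_akap.tsv"
  df <- read.delim(ext(f), sep = "\t", stringsAsFactors = FALSE,
                   na.strings = "", colClasses = "character")
  for (col in lesion_labels()) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
  }
  vals <- unlist(lapply(df[lesion_labels()], vaf_values))
  if (length(vals) && (any(vals < 0) || any(vals > 1))) {
    stop("fixture VAF outside [0,1]", call. = FALSE)
  }
  class(df) <- c("mutation_table", "data.frame")
  df
}

#' Lesion labels in temporal order
#' @return `c("primary", "axillary", "metastasis_1", "metastasis_2")`
#' @export
lesion_labels <- function() {
  c("primary", "axillary", "metastasis_1", "metastasis_2")
}

#' Parse a (possibly multi-block) VAF cell
#'
#' Mutation-table VAF cells are stored as character: `""`/`NA` for "not
#' assayed", a single fraction, or a `;`-separated list when several
#' tissue blocks of one sample were assayed.
#'
#' @param x character vector of cells.
#' @return numeric vector of all parsed values (empty cells dropped).
#' @export
vaf_values <- function(x) {
  x <- x[!is.na(x) & nzchar(x)]
  if (!length(x)) return(numeric())
  as.numeric(unlist(strsplit(x, ";", fixed = TRUE)))
}

#' Maximum VAF of a cell, `NA` for a missing cell
#' @rdname vaf_values
#' @export
vaf_max <- function(x) {
  vapply(x, function(cell) {
    v <- vaf_values(cell)
    if (length(v)) max(v) else NA_real_
  }, numeric(1), USE.NAMES = FALSE)
}
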