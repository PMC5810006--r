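#' Somatic filtering thresholds
#'
#' Threshold set for the somatic-call filters. Defaults reproduce the
#' published rules: germline VAF < 1\%, tumor variant reads >= 5, total
#' tumor coverage > 30 (exclusive), exome-wide VAF > 16\% (exclusive),
#' and at least one alternate read on each strand. `max_germline_alt`
#' is the programmatic stand-in for the manual "variant reads in normal
#' sample" review: more than this many germline alternate reads rejects
#' the call even when the germline VAF rule passes.
#'
#' @param max_germline_vaf germline VAF must be strictly below this.
#' @param min_tumor_alt_reads minimum tumor alternate reads (inclusive).
#' @param min_coverage tumor coverage must strictly exceed this.
#' @param min_exomewide_vaf tumor VAF must strictly exceed this for the
#'   exome-wide tier.
#' @param min_strand_reads minimum alternate reads required per strand.
#' @param max_germline_alt maximum tolerated germline alternate reads.
#' @return a list of class `filter_config`.
#' @export
filter_config <- function(max_germline_vaf = 0.01,
                          min_tumor_alt_reads = 5,
                          min_coverage = 30,
                          min_exomewide_vaf = 0.16,
                          min_strand_reads = 1,
                          max_germline_alt = 1) {
  cfg <- list(max_germline_vaf = max_germline_vaf,
              min_tumor_alt_reads = min_tumor_alt_reads,
              min_coverage = min_coverage,
              min_exomewide_vaf = min_exomewide_vaf,
              min_strand_reads = min_strand_reads,
              max_germline_alt = max_germline_alt)
  num <- vapply(cfg, function(v) is.numeric(v) && length(v) == 1 &&
                  is.finite(v) && v >= 0, logical(1))
  if (!all(num)) stop("all thresholds must be single non-negative numbers",
                      call. = FALSE)
  if (max_germline_vaf > 1 || min_exomewide_vaf > 1) {
    stop("VAF thresholds must lie in [0, 1]", call. = FALSE)
  }
  class(cfg) <- "filter_config"
  cfg
}

#' Apply the somatic filtering rules
#'
#' Evaluates every rule on every record and returns a verdict table.
#' A record is kept in the `exome_wide` tier when all of the following
#' hold: germline VAF strictly below `max_germline_vaf`; tumor
#' alternate reads at least `min_tumor_alt_reads`; tumor coverage
#' strictly above `min_coverage`; tumor VAF strictly above
#' `min_exomewide_vaf`; no QC flag (`normal_support`, `single_strand`)
#' fires. Records with zero tumor coverage are never kept and carry the
#' single reason `not_evaluable`. Missing strand counts do not reject:
#' the strand rule is reported as not evaluable via the
#' `strand_evaluable` column.
#'
#' @param records a [variant_table()].
#' @param config a [filter_config()].
#' @return data frame with one row per record: `kept`, `tier`
#'   (`exome_wide` or `rejected`), `reasons` (comma-separated rule ids,
#'   empty when kept) and `strand_evaluable`.
#' @export
filter_somatic <- function(records, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  n <- nrow(records)
  g_tot <- records$germline_ref + records$germline_alt
  t_tot <- records$tumor_ref + records$tumor_alt
  g_vaf <- ifelse(g_tot > 0, records$germline_alt / g_tot, 0)
  t_vaf <- ifelse(t_tot > 0, records$tumor_alt / t_tot, NA_real_)
  strand_ok_known <- is.finite(records$tumor_alt_fwd) &
    is.finite(records$tumor_alt_rev)

  fails <- list(
    germline_vaf = g_vaf >= config$max_germline_vaf,
    low_alt_reads = records$tumor_alt < config$min_tumor_alt_reads,
    low_coverage = t_tot <= config$min_coverage,
    low_vaf = !is.na(t_vaf) & t_vaf <= config$min_exomewide_vaf,
    normal_support = records$germline_alt > config$max_germline_alt,
    single_strand = strand_ok_known & records$tumor_alt > 0 &
      (records$tumor_alt_fwd < config$min_strand_reads |
         records$tumor_alt_rev < config$min_strand_reads)
  )
  not_eval <- t_tot == 0
  reasons <- vapply(seq_len(n), function(i) {
    if (not_eval[i]) return("not_evaluable")
    r <- names(fails)[vapply(fails, `[`, logical(1), i)]
    paste(r, collapse = ",")
  }, character(1))
  kept <- !not_eval & !nzchar(reasons)
  data.frame(
    kept = kept,
    tier = ifelse(kept, "exome_wide", "rejected"),
    reasons = reasons,
    strand_evaluable = strand_ok_known,
    stringsAsFactors = FALSE)
}

#' Shared-position selection for paired lesions
#'
#' For genes in a candidate panel, a variant position observed in either
#' lesion of a pair is retained even when its tumor alternate reads fall
#' below `min_tumor_alt_reads` in one (or both) lesions, so that true
#' shared low-frequency mutations are not excluded. Germline-VAF,
#' coverage and QC rules still apply in the lesion(s) where the variant
#' was observed. Positions are matched on (chrom, pos, ref, alt).
#'
#' @param primary,metastasis [variant_table()]s from the same patient.
#' @param gene_panel character vector of panel gene symbols; if empty,
#'   all genes are considered, with a warning.
#' @param config a [filter_config()].
#' @return data frame with one row per retained position: identity
#'   columns, per-lesion alt reads and VAF, and `status` in
#'   `shared` / `primary_only` / `metastasis_only`.
#' @export
select_shared_positions <- function(primary, metastasis,
                                    gene_panel = akap_genes(),
                                    config = filter_config()) {
  if (length(gene_panel) == 0) {
    warning("empty gene panel: reporting over all genes")
    gene_panel <- unique(c(primary$gene, metastasis$gene))
  }
  key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
  # relaxed rule set: drop the alt-read and VAF requirements
  relaxed <- config
  relaxed$min_tumor_alt_reads <- 0
  relaxed$min_exomewide_vaf <- 0
  class(relaxed) <- "filter_config"
  pass <- function(tbl) {
    if (nrow(tbl) == 0) return(logical(0))
    v <- filter_somatic(tbl, relaxed)
    v$kept & tbl$gene %in% gene_panel & tbl$tumor_alt > 0
  }
  p_ok <- pass(primary); m_ok <- pass(metastasis)
  pk <- key(primary)[p_ok]; mk <- key(metastasis)[m_ok]
  all_keys <- union(pk, mk)
  if (!length(all_keys)) {
    return(data.frame(chrom = character(), pos = numeric(),
                      ref = character(), alt = character(),
                      gene = character(),
                      primary_alt = numeric(), metastasis_alt = numeric(),
                      primary_vaf = numeric(), metastasis_vaf = numeric(),
                      status = character(), tier = character(),
                      stringsAsFactors = FALSE))
  }
  pi <- match(all_keys, key(primary))
  mi <- match(all_keys, key(metastasis))
  src <- ifelse(!is.na(pi), "p", "m")
  take <- function(col) ifelse(src == "p", primary[[col]][pi],
                               metastasis[[col]][mi])
  p_alt <- ifelse(is.na(pi), 0, primary$tumor_alt[pi])
  m_alt <- ifelse(is.na(mi), 0, metastasis$tumor_alt[mi])
  status <- ifelse(all_keys %in% pk & all_keys %in% mk, "shared",
                   ifelse(all_keys %in% pk, "primary_only",
                          "metastasis_only"))
  out <- data.frame(
    chrom = take("chrom"), pos = take("pos"),
    ref = take("ref"), alt = take("alt"), gene = take("gene"),
    primary_alt = p_alt, metastasis_alt = m_alt,
    primary_vaf = ifelse(is.na(pi), NA_real_, tumor_vaf(primary)[pi]),
    metastasis_vaf = ifelse(is.na(mi), NA_real_, tumor_vaf(metastasis)[mi]),
    status = status,
    tier = "candidate_gene_shared",
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

TRANSITIONS <- c("A>G", "G>A", "C>T", "T>C")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")
PYRIMIDINE_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Substitution spectrum and Ti/Tv ratio
#'
#' Counts transitions (A<->G, C<->T) and transversions over
#' single-nucleotide substitutions and folds purine-context classes
#' onto the six pyrimidine-context classes (e.g. G>A is counted as
#' C>T). Non-SNV rows are skipped and counted.
#'
#' @param records a [variant_table()], or a character vector of
#'   substitutions like `"G>A"`.
#' @return list of class `spectrum_summary`: `transitions`,
#'   `transversions`, `titv_ratio` (`NA` with `titv_defined = FALSE`
#'   when there are no transversions), `per_substitution_counts`
#'   (named over the six pyrimidine classes), `n_skipped`.
#' @export
substitution_spectrum <- function(records) {
  subs <- if (is.character(records)) records else
    paste0(records$ref, ">", records$alt)
  parts <- strsplit(subs, ">", fixed = TRUE)
  ok <- vapply(parts, function(p) {
    length(p) == 2 && all(p %in% names(COMPLEMENT)) && p[1] != p[2]
  }, logical(1))
  n_skipped <- sum(!ok)
  subs <- subs[ok]
  ti <- sum(subs %in% TRANSITIONS)
  tv <- length(subs) - ti
  folded <- vapply(strsplit(subs, ">", fixed = TRUE), function(p) {
    if (p[1] %in% c("G", "A")) {
      paste0(COMPLEMENT[[p[1]]], ">", COMPLEMENT[[p[2]]])
    } else paste0(p[1], ">", p[2])
  }, character(1))
  counts <- setNames(integer(length(PYRIMIDINE_CLASSES)),
                     PYRIMIDINE_CLASSES)
  tab <- table(folded)
  counts[names(tab)] <- as.integer(tab)
  structure(list(
    transitions = ti, transversions = tv,
    titv_ratio = if (tv > 0) ti / tv else NA_real_,
    titv_defined = tv > 0,
    per_substitution_counts = counts,
    n_skipped = n_skipped), class = "spectrum_summary")
}

#' Pooled-variance two-sample Student t test
#'
#' Classic textbook form (equal-variance assumption). Degenerate inputs
#' with zero pooled variance yield t = 0, p = 1 when the means are
#' equal, and |t| = Inf, p = 0 otherwise.
#'
#' @param x,y numeric vectors (each length >= 2).
#' @return list with `t`, `df`, `p_value`, `mean_x`, `mean_y`.
#' @export
pooled_t_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 observations",
                             call. = FALSE)
  m1 <- mean(x); m2 <- mean(y)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  if (se == 0) {
    t <- if (m1 == m2) 0 else sign(m1 - m2) * Inf
    p <- if (m1 == m2) 1 else 0
  } else {
    t <- (m1 - m2) / se
    p <- 2 * stats::pt(-abs(t), df)
  }
  list(t = t, df = df, p_value = p, mean_x = m1, mean_y = m2)
}

#' Per-compartment mutation load with a two-sample comparison
#'
#' Counts filtered mutations per patient and compartment (optionally
#' restricted to a gene list and to a consequence class) and compares
#' two compartments with the pooled-variance Student t test. A
#' compartment with fewer than two patients suppresses the comparison;
#' the counts are still returned.
#'
#' @param records a [variant_table()] pooled over patients; patients are
#'   identified by `sample_id`.
#' @param compartments length-2 character vector to compare.
#' @param genes optional restriction to a gene list (e.g. a
#'   recurrent-gene panel).
#' @param consequence optional restriction (default `"nonsynonymous"`;
#'   use `NULL` for all).
#' @return list of class `mutation_load_summary`: `per_patient` (data
#'   frame patient x compartment count), `group_stats` (mean and range
#'   per compartment), `test` (from [pooled_t_test()], or `NULL`).
#' @export
mutation_load_summary <- function(records,
                                  compartments = c("primary", "metastasis"),
                                  genes = NULL,
                                  consequence = "nonsynonymous") {
  stopifnot(length(compartments) == 2)
  keep <- records$compartment %in% compartments
  if (!is.null(genes)) keep <- keep & records$gene %in% genes
  if (!is.null(consequence)) {
    keep <- keep & records$consequence %in% consequence
  }
  r <- records[keep, , drop = FALSE]
  patients <- sort(unique(records$sample_id[records$compartment %in%
                                              compartments]))
  counts <- lapply(compartments, function(cp) {
    vapply(patients, function(p)
      sum(r$sample_id == p & r$compartment == cp), numeric(1))
  })
  names(counts) <- compartments
  per_patient <- data.frame(patient = patients,
                            counts[[1]], counts[[2]],
                            stringsAsFactors = FALSE, row.names = NULL)
  names(per_patient)[2:3] <- compartments
  group_stats <- data.frame(
    compartment = compartments,
    n = vapply(counts, length, numeric(1)),
    mean = vapply(counts, function(v) if (length(v)) mean(v) else NA_real_,
                  numeric(1)),
    min = vapply(counts, function(v) if (length(v)) min(v) else NA_real_,
                 numeric(1)),
    max = vapply(counts, function(v) if (length(v)) max(v) else NA_real_,
                 numeric(1)),
    row.names = NULL)
  test <- if (all(vapply(counts, length, numeric(1)) >= 2)) {
    pooled_t_test(counts[[1]], counts[[2]])
  } else NULL
  structure(list(per_patient = per_patient, group_stats = group_stats,
                 test = test), class = "mutation_load_summary")
}
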