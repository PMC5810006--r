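#' Summarize a gene-family mutation table
#'
#' Classifies each mutation of a table (e.g. the packaged AKAP tables)
#' as `primary_only`, `metastasis_only` or `shared`, and collects the
#' mutated genes and patients. A mutation is considered present in a
#' lesion when its VAF there strictly exceeds `presence_threshold`
#' (default 0: any reported non-zero VAF counts, matching tables where
#' absence is printed as 0\%). Missing ("not assayed") cells count as
#' absence for classification. Axillary and both metastasis columns
#' count as metastatic lesions. Multi-block cells use the maximum VAF.
#'
#' @param rows a `mutation_table` (see [load_fixture()]).
#' @param presence_threshold VAF presence cutoff.
#' @return list of class `mutation_table_summary`: `total_mutations`,
#'   `metastasis_only`, `primary_only`, `shared`, `genes_mutated`,
#'   `patients_mutated`, `per_patient` (data frame patient x
#'   primary/metastasis presence).
#' @examples
#' summarize_mutation_table(load_fixture("cohort1_akap"))
#' @export
summarize_mutation_table <- function(rows, presence_threshold = 0) {
  met_cols <- c("axillary", "metastasis_1", "metastasis_2")
  n <- nrow(rows)
  if (n == 0) {
    return(structure(list(
      total_mutations = 0L, metastasis_only = 0L, primary_only = 0L,
      shared = 0L, genes_mutated = character(),
      patients_mutated = character(),
      per_patient = data.frame(patient = character(),
                               primary = logical(),
                               metastasis = logical())),
      class = "mutation_table_summary"))
  }
  p_vaf <- vaf_max(rows$primary)
  vm <- matrix(vapply(met_cols, function(cl) vaf_max(rows[[cl]]),
                      numeric(n)), nrow = n)
  m_vaf <- apply(vm, 1, function(v) {
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  })
  in_p <- !is.na(p_vaf) & p_vaf > presence_threshold
  in_m <- !is.na(m_vaf) & m_vaf > presence_threshold
  class_of <- ifelse(in_p & in_m, "shared",
                     ifelse(in_p, "primary_only", "metastasis_only"))
  patients <- unique(rows$patient)
  per_patient <- data.frame(
    patient = patients,
    primary = vapply(patients, function(p) any(in_p[rows$patient == p]),
                     logical(1)),
    metastasis = vapply(patients, function(p) any(in_m[rows$patient == p]),
                        logical(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(
    total_mutations = n,
    metastasis_only = sum(class_of == "metastasis_only"),
    primary_only = sum(class_of == "primary_only"),
    shared = sum(class_of == "shared"),
    genes_mutated = sort(unique(rows$gene)),
    patients_mutated = sort(unique(rows$patient)),
    per_patient = per_patient), class = "mutation_table_summary")
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p-value by probability ordering: with all margins
#' fixed, the p-value sums the hypergeometric probabilities of every
#' table whose probability does not exceed that of the observed table
#' (within a relative tolerance of 1e-7, the usual guard against
#' floating-point ties). A zero margin gives p = 1 with a flag. The
#' odds ratio is the sample OR `(ad)/(bc)`, flagged when a zero cell
#' makes it 0 or infinite.
#'
#' @param counts 2x2 matrix (or coercible) of non-negative integers;
#'   conventionally compartment (rows) x mutated-status (columns).
#' @return list of class `enrichment_result`: `table`, `p_two_sided`,
#'   `odds_ratio`, `zero_margin`, `zero_cell`.
#' @examples
#' fisher_family_enrichment(matrix(c(8, 1, 50, 120), nrow = 2))
#' @export
fisher_family_enrichment <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2)) || any(counts < 0) ||
      any(counts != floor(counts))) {
    stop("counts must be a 2x2 matrix of non-negative integers",
         call. = FALSE)
  }
  a <- counts[1, 1]
  r1 <- sum(counts[1, ]); r2 <- sum(counts[2, ])
  c1 <- sum(counts[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(counts[, 2]) == 0) {
    return(structure(list(table = counts, p_two_sided = 1,
                          odds_ratio = NA_real_, zero_margin = TRUE,
                          zero_cell = any(counts == 0)),
                     class = "enrichment_result"))
  }
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- (counts[1, 1] * counts[2, 2]) / (counts[1, 2] * counts[2, 1])
  structure(list(table = counts, p_two_sided = min(p, 1),
                 odds_ratio = or, zero_margin = FALSE,
                 zero_cell = any(counts == 0)),
            class = "enrichment_result")
}

#' Per-(patient, gene) VAF trajectories across sequential lesions
#'
#' Orders each mutation's VAFs along the fixed temporal lesion order
#' primary -> axillary -> metastasis_1 -> metastasis_2 (non-missing
#' entries only; multi-block cells use the maximum) and flags
#' trajectories whose VAF never decreases.
#'
#' @param rows a `mutation_table`.
#' @return data frame: `patient`, `gene`, `trajectory` (lesion=VAF
#'   pairs as text), `n_lesions`, `monotone_increasing` (non-strict).
#' @examples
#' vaf_trajectories(load_fixture("cohort2_akap"))
#' @export
vaf_trajectories <- function(rows) {
  res <- lapply(seq_len(nrow(rows)), function(i) {
    vafs <- vaf_max(unlist(rows[i, lesion_labels()]))
    keep <- !is.na(vafs)
    v <- vafs[keep]; lab <- lesion_labels()[keep]
    data.frame(
      patient = rows$patient[i], gene = rows$gene[i],
      trajectory = paste(sprintf("%s=%.3g", lab, v), collapse = " -> "),
      n_lesions = length(v),
      monotone_increasing = length(v) < 2 || !any(diff(v) < 0),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Gene-family mutation prevalence per compartment
#'
#' Fraction of patients carrying at least one family mutation in their
#' primary (resp. any metastatic) lesion, pooled over one or more
#' cohort summaries.
#'
#' @param cohort_summaries a list of `mutation_table_summary` objects
#'   (a single summary is also accepted).
#' @param n_patients total number of patients in the pooled cohorts.
#' @return list: `primary`, `metastasis` (fractions),
#'   `n_patients_primary`, `n_patients_metastasis`, `n_patients`.
#' @examples
#' s1 <- summarize_mutation_table(load_fixture("cohort1_akap"))
#' s2 <- summarize_mutation_table(load_fixture("cohort2_akap"))
#' family_prevalence(list(s1, s2), n_patients = 30)
#' @export
family_prevalence <- function(cohort_summaries, n_patients) {
  if (inherits(cohort_summaries, "mutation_table_summary")) {
    cohort_summaries <- list(cohort_summaries)
  }
  stopifnot(n_patients > 0)
  pp <- do.call(rbind, lapply(cohort_summaries, `[[`, "per_patient"))
  n_p <- if (is.null(pp)) 0L else sum(pp$primary)
  n_m <- if (is.null(pp)) 0L else sum(pp$metastasis)
  list(primary = n_p / n_patients, metastasis = n_m / n_patients,
       n_patients_primary = n_p, n_patients_metastasis = n_m,
       n_patients = n_patients)
}
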