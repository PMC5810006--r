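#' Gene universe for somatic simulation
#'
#' A synthetic stand-in for a recurrently-mutated-gene panel of ~505
#' symbols (the actual published list is not printed anywhere): the 14
#' AKAP family genes plus 491 generated symbols `RMG001` ...
#'
#' @return character vector of 505 gene symbols.
#' @export
recurrent_gene_universe <- function() {
  c(akap_genes(), sprintf("RMG%03d", 1:491))
}

#' Simulation parameters for a paired exome case
#'
#' Encodes the statistical structure the downstream stages assume:
#' heterozygous germline SNPs at ~50\% allele fraction, tumor purity
#' diluting copy-neutral LOH, whole-genome-amplification allelic
#' dropout, CNV segments scaling coverage, and compartment-specific
#' somatic mutation rates with optional gene-family enrichment in the
#' metastasis.
#'
#' Defaults state a plausible discovery-cohort-like world: 5000
#' heterozygous SNPs over 4 chromosomes at 100x mean depth, purity 0.8,
#' dropout 5\% (the published metastasis false-negative fractions
#' average ~4.9\%), no LOH and no CNV unless requested, and 6 vs 24
#' expected recurrent-gene mutations in primary vs metastasis (the
#' published per-patient averages).
#'
#' @param n_snps number of germline-heterozygous SNPs.
#' @param n_chrom number of chromosomes the SNPs are spread over.
#' @param snp_spacing distance in bp between adjacent SNPs.
#' @param mean_depth mean sequencing depth (Poisson).
#' @param purity tumor cell fraction rho in (0, 1].
#' @param loh_regions [region_set()] of copy-neutral LOH blocks (must
#'   be non-overlapping); shared by primary and metastasis, with the
#'   same retained haplotype (the phase-concordance signal).
#' @param dropout_rate probability a het SNP suffers WGA allelic
#'   imbalance, independently per tumor compartment.
#' @param dropout_bias shift of the biased allele fraction: affected
#'   SNPs sample reads at 0.5 +/- `dropout_bias`.
#' @param cnv_segments data frame `chrom`, `start`, `end`,
#'   `copy_number` (diploid baseline 2); applies to both tumor
#'   compartments.
#' @param somatic_rate_primary,somatic_rate_metastasis expected somatic
#'   mutation counts per compartment.
#' @param family_genes gene-family symbols (default the 14 AKAPs).
#' @param family_enrichment_multiplier >= 1; upweights family genes
#'   when drawing metastasis-specific mutations.
#' @param shared_fraction fraction of somatic mutations present in both
#'   lesions.
#' @param sample_id patient label.
#' @param seed integer seed; identical seeds give identical cases.
#' @return list of class `simulation_params`.
#' @export
simulation_params <- function(n_snps = 5000, n_chrom = 4,
                              snp_spacing = 3000, mean_depth = 100,
                              purity = 0.8,
                              loh_regions = region_set(),
                              dropout_rate = 0.05, dropout_bias = 0.45,
                              cnv_segments = NULL,
                              somatic_rate_primary = 6,
                              somatic_rate_metastasis = 24,
                              family_genes = akap_genes(),
                              family_enrichment_multiplier = 1,
                              shared_fraction = 0.2,
                              sample_id = "case1", seed = 1) {
  stopifnot(n_snps >= 1, n_chrom >= 1, mean_depth > 0,
            purity > 0, purity <= 1,
            dropout_rate >= 0, dropout_rate <= 1,
            dropout_bias >= 0, dropout_bias <= 0.5,
            shared_fraction >= 0, shared_fraction <= 1,
            family_enrichment_multiplier >= 1)
  assert_disjoint(loh_regions, "loh_regions")
  if (is.null(cnv_segments)) {
    cnv_segments <- data.frame(chrom = character(), start = numeric(),
                               end = numeric(), copy_number = numeric())
  }
  if (nrow(cnv_segments) && any(cnv_segments$copy_number < 0)) {
    stop("copy_number must be >= 0", call. = FALSE)
  }
  structure(list(
    n_snps = n_snps, n_chrom = n_chrom, snp_spacing = snp_spacing,
    mean_depth = mean_depth, purity = purity, loh_regions = loh_regions,
    dropout_rate = dropout_rate, dropout_bias = dropout_bias,
    cnv_segments = cnv_segments,
    somatic_rate_primary = somatic_rate_primary,
    somatic_rate_metastasis = somatic_rate_metastasis,
    family_genes = family_genes,
    family_enrichment_multiplier = family_enrichment_multiplier,
    shared_fraction = shared_fraction,
    sample_id = sample_id, seed = seed), class = "simulation_params")
}

#' Simulate a paired germline/primary/metastasis exome case
#'
#' Draws a complete case under [simulation_params()]:
#' \itemize{
#'   \item germline het SNPs: depth ~ Poisson(`mean_depth`), alternate
#'     reads ~ Binomial(depth, 0.5);
#'   \item tumor compartments: per-SNP depth ~ Poisson(`mean_depth` x
#'     copy_number / 2); inside `loh_regions` the expected fraction of
#'     the retained allele is `(1 + purity) / 2` (copy-neutral LOH,
#'     one retained haplotype per region shared by both compartments);
#'   \item dropout: each SNP is independently perturbed with
#'     probability `dropout_rate` to an allele fraction of
#'     `0.5 +/- dropout_bias` (random direction), per compartment;
#'   \item somatic variants: Poisson counts split into shared /
#'     primary-only / metastasis-only categories, genes drawn from
#'     [recurrent_gene_universe()] with family genes upweighted by
#'     `family_enrichment_multiplier` for metastasis-specific draws,
#'     VAF = purity x clonality / 2 with clonality ~ U(0.2, 1).
#' }
#'
#' @param params a [simulation_params()].
#' @return list of class `simulated_case`: `germline`, `primary`,
#'   `metastasis` ([snp_table()]s), `primary_variants`,
#'   `metastasis_variants` ([variant_table()]s), `truth` (params,
#'   per-SNP indicator table, injected somatic list).
#' @export
simulate_case <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  with_local_seed(params$seed, simulate_case_impl(params))
}

simulate_case_impl <- function(p) {
  per_chr <- ceiling(p$n_snps / p$n_chrom)
  chrom <- rep(paste0("chr", seq_len(p$n_chrom)),
               each = per_chr)[seq_len(p$n_snps)]
  pos <- unlist(lapply(table(factor(chrom, levels = unique(chrom))),
                       function(k) p$snp_spacing * seq_len(k)),
                use.names = FALSE)
  n <- p$n_snps

  in_loh <- in_regions(chrom, pos, p$loh_regions)
  loh_idx <- region_index(chrom, pos, p$loh_regions)
  retained_by_region <- if (nrow(p$loh_regions))
    sample(c("ref", "alt"), nrow(p$loh_regions), replace = TRUE)
  else character()
  retained <- ifelse(in_loh, retained_by_region[loh_idx], NA_character_)

  cn <- rep(2, n)
  if (nrow(p$cnv_segments)) {
    for (i in seq_len(nrow(p$cnv_segments))) {
      seg <- p$cnv_segments[i, ]
      m <- chrom == seg$chrom & (pos - 1) >= seg$start & (pos - 1) < seg$end
      cn[m] <- seg$copy_number
    }
  }

  g_depth <- rpois(n, p$mean_depth)
  g_alt <- rbinom(n, g_depth, 0.5)
  germline <- snp_table(chrom, pos, g_depth - g_alt, g_alt, "germline")

  draw_tumor <- function(compartment) {
    depth <- rpois(n, p$mean_depth * cn / 2)
    p_alt <- rep(0.5, n)
    p_alt[in_loh & retained == "alt"] <- (1 + p$purity) / 2
    p_alt[in_loh & retained == "ref"] <- (1 - p$purity) / 2
    drop <- runif(n) < p$dropout_rate
    dir <- sample(c(-1, 1), n, replace = TRUE)
    p_alt[drop] <- 0.5 + dir[drop] * p$dropout_bias
    alt <- rbinom(n, depth, p_alt)
    list(tbl = snp_table(chrom, pos, depth - alt, alt, compartment),
         dropout = drop)
  }
  prim <- draw_tumor("primary")
  met <- draw_tumor("metastasis")

  somatic <- draw_somatic(p, chrom)
  list2 <- function(cat_keep) {
    somatic[somatic$category %in% cat_keep, , drop = FALSE]
  }
  primary_variants <- somatic_to_variants(
    list2(c("shared", "primary_only")), p, "primary")
  metastasis_variants <- somatic_to_variants(
    list2(c("shared", "metastasis_only")), p, "metastasis")

  structure(list(
    germline = germline, primary = prim$tbl, metastasis = met$tbl,
    primary_variants = primary_variants,
    metastasis_variants = metastasis_variants,
    truth = list(
      params = p,
      snps = data.frame(chrom = chrom, pos = pos, in_loh = in_loh,
                        retained = retained, copy_number = cn,
                        dropout_primary = prim$dropout,
                        dropout_metastasis = met$dropout,
                        stringsAsFactors = FALSE),
      somatic = somatic)), class = "simulated_case")
}

draw_somatic <- function(p, snp_chrom) {
  universe <- recurrent_gene_universe()
  fam <- universe %in% p$family_genes
  shared_e <- p$shared_fraction * min(p$somatic_rate_primary,
                                      p$somatic_rate_metastasis)
  n_shared <- rpois(1, shared_e)
  n_p_only <- rpois(1, max(p$somatic_rate_primary - shared_e, 0))
  n_m_only <- rpois(1, max(p$somatic_rate_metastasis - shared_e, 0))
  w_met <- ifelse(fam, p$family_enrichment_multiplier, 1)
  pick <- function(k, w = NULL) {
    if (k == 0) return(character())
    sample(universe, k, replace = TRUE, prob = w)
  }
  genes <- c(pick(n_shared), pick(n_p_only), pick(n_m_only, w_met))
  k <- length(genes)
  chroms <- unique(snp_chrom)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, k, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  df <- data.frame(
    category = rep(c("shared", "primary_only", "metastasis_only"),
                   c(n_shared, n_p_only, n_m_only)),
    gene = genes,
    chrom = if (k) sample(chroms, k, replace = TRUE) else character(),
    pos = if (k) round(runif(k, 1, 3e7)) else numeric(),
    ref = ref, alt = alt,
    consequence = if (k) sample(c("nonsynonymous", "synonymous", "nonsense"),
                                k, replace = TRUE,
                                prob = c(0.7, 0.25, 0.05)) else character(),
    stringsAsFactors = FALSE)
  df
}

somatic_to_variants <- function(somatic, p, compartment) {
  k <- nrow(somatic)
  if (k == 0) {
    return(variant_table(data.frame(
      chrom = character(), pos = numeric(), ref = character(),
      alt = character(), germline_ref = numeric(),
      germline_alt = numeric(), tumor_ref = numeric(),
      tumor_alt = numeric(), tumor_alt_fwd = numeric(),
      tumor_alt_rev = numeric(), gene = character(),
      consequence = character(), sample_id = character(),
      compartment = character(), stringsAsFactors = FALSE)))
  }
  clonality <- runif(k, 0.2, 1)
  vaf <- p$purity * clonality / 2
  t_depth <- rpois(k, p$mean_depth)
  t_alt <- rbinom(k, t_depth, vaf)
  g_depth <- rpois(k, p$mean_depth)
  g_alt <- rbinom(k, g_depth, 0.001)
  fwd <- rbinom(k, t_alt, 0.5)
  variant_table(data.frame(
    chrom = somatic$chrom, pos = somatic$pos,
    ref = somatic$ref, alt = somatic$alt,
    germline_ref = g_depth - g_alt, germline_alt = g_alt,
    tumor_ref = t_depth - t_alt, tumor_alt = t_alt,
    tumor_alt_fwd = fwd, tumor_alt_rev = t_alt - fwd,
    gene = somatic$gene, consequence = somatic$consequence,
    sample_id = p$sample_id, compartment = compartment,
    stringsAsFactors = FALSE))
}

#' Ground-truth report for a simulated case
#'
#' The oracle for recovery tests: realized (not just nominal) values of
#' every quantity the downstream estimators target.
#'
#' @param case a `simulated_case`.
#' @return list: `realized_loh_fraction`; per-compartment
#'   `realized_dropout` (overall and among non-LOH SNPs); injected
#'   `cnv_segments`; somatic counts per compartment and per
#'   family/non-family.
#' @export
truth_report <- function(case) {
  stopifnot(inherits(case, "simulated_case"))
  s <- case$truth$snps
  som <- case$truth$somatic
  p <- case$truth$params
  fam <- som$gene %in% p$family_genes
  in_comp <- function(comp) {
    som$category == "shared" | som$category == paste0(comp, "_only")
  }
  list(
    realized_loh_fraction = mean(s$in_loh),
    realized_dropout = list(
      primary = mean(s$dropout_primary),
      metastasis = mean(s$dropout_metastasis),
      primary_non_loh = mean(s$dropout_primary[!s$in_loh]),
      metastasis_non_loh = mean(s$dropout_metastasis[!s$in_loh])),
    cnv_segments = p$cnv_segments,
    somatic_counts = data.frame(
      compartment = c("primary", "metastasis"),
      total = c(sum(in_comp("primary")), sum(in_comp("metastasis"))),
      family = c(sum(in_comp("primary") & fam),
                 sum(in_comp("metastasis") & fam)),
      non_family = c(sum(in_comp("primary") & !fam),
                     sum(in_comp("metastasis") & !fam))))
}
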