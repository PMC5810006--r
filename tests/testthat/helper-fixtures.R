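# small builders shared across test files

# one-or-more-row variant table with sensible defaults
vrec <- function(chrom = "chr1", pos = 100, ref = "G", alt = "A",
                 germline_ref = 200, germline_alt = 0,
                 tumor_ref = 32, tumor_alt = 8,
                 tumor_alt_fwd = NA, tumor_alt_rev = NA,
                 gene = "", consequence = "nonsynonymous",
                 sample_id = "s1", compartment = "primary") {
  variant_table(data.frame(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    germline_ref = germline_ref, germline_alt = germline_alt,
    tumor_ref = tumor_ref, tumor_alt = tumor_alt,
    tumor_alt_fwd = tumor_alt_fwd, tumor_alt_rev = tumor_alt_rev,
    gene = gene, consequence = consequence,
    sample_id = sample_id, compartment = compartment,
    stringsAsFactors = FALSE))
}

# snp table over n positions on one chromosome
snps <- function(ref_count, alt_count, chrom = "chr1",
                 pos = seq_along(ref_count) * 1000, sample_id = "s") {
  snp_table(chrom, pos, ref_count, alt_count, sample_id)
}

# a region_set covering the first `k` simulated SNPs (the simulator lays
# out n_snps over n_chrom chromosomes, `per` SNPs each, spacing bp apart)
loh_regions_covering <- function(k, n_snps = 5000, n_chrom = 4,
                                 spacing = 3000) {
  per <- ceiling(n_snps / n_chrom)
  chroms <- character(); starts <- numeric(); ends <- numeric()
  i <- 1
  while (k > 0 && i <= n_chrom) {
    take <- min(k, per)
    chroms <- c(chroms, paste0("chr", i))
    starts <- c(starts, 0)
    ends <- c(ends, take * spacing + 1)
    k <- k - take
    i <- i + 1
  }
  region_set(chroms, starts, ends)
}

# maf_table with given major-allele pattern (for concordance tests)
maf_obs <- function(major, maf = 0.9, chrom = "chr1",
                    pos = seq_along(major) * 100) {
  structure(data.frame(chrom = chrom, pos = pos, maf = maf,
                       major_allele = major, coverage = 100,
                       stringsAsFactors = FALSE),
            class = c("maf_table", "data.frame"))
}

# exact upper-tail binomial(n, 1/2) by enumeration of all 2^n outcomes
enumerate_p_upper <- function(n, k) {
  succ <- vapply(0:(2^n - 1), function(o)
    sum(as.integer(intToBits(o))[seq_len(n)]), integer(1))
  sum(succ >= k) / 2^n
}

# two-sided Fisher p by direct enumeration over all tables with the
# observed margins (probability ordering)
enumerate_fisher_p <- function(tab) {
  a <- tab[1, 1]; r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  prob <- vapply(support, function(x) {
    choose(r1, x) * choose(r2, c1 - x) / choose(n, c1)
  }, numeric(1))
  p_obs <- prob[support == a]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}
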