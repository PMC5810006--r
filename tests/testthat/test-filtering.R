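test_that("filter_somatic applies the published rules", {
  cfg <- filter_config()

  # all rules pass: germline VAF 0.005, alt 8/40, VAF 0.2, both strands
  v <- vrec(germline_ref = 199, germline_alt = 1,
            tumor_ref = 32, tumor_alt = 8,
            tumor_alt_fwd = 4, tumor_alt_rev = 4)
  out <- filter_somatic(v, cfg)
  expect_true(out$kept)
  expect_equal(out$tier, "exome_wide")
  expect_equal(out$reasons, "")

  # germline VAF 0.02 -> rejected for exactly that rule
  out <- filter_somatic(vrec(germline_ref = 98, germline_alt = 2,
                             tumor_ref = 32, tumor_alt = 8,
                             tumor_alt_fwd = 4, tumor_alt_rev = 4), cfg)
  expect_false(out$kept)
  expect_equal(out$reasons, "germline_vaf,normal_support")

  # all alternate reads on one strand
  out <- filter_somatic(vrec(tumor_ref = 24, tumor_alt = 6,
                             tumor_alt_fwd = 6, tumor_alt_rev = 0), cfg)
  expect_match(out$reasons, "single_strand")

  # exclusive bounds: coverage exactly 30 and VAF exactly 16% both fail
  out <- filter_somatic(vrec(tumor_ref = 25, tumor_alt = 5), cfg)
  expect_match(out$reasons, "low_coverage")
  out <- filter_somatic(vrec(tumor_ref = 84, tumor_alt = 16), cfg)
  expect_match(out$reasons, "low_vaf")

  # zero tumor coverage is not evaluable, never a crash
  out <- filter_somatic(vrec(tumor_ref = 0, tumor_alt = 0), cfg)
  expect_false(out$kept)
  expect_equal(out$reasons, "not_evaluable")

  # missing strand counts: rule reported not evaluable, no rejection
  out <- filter_somatic(vrec(tumor_ref = 32, tumor_alt = 8), cfg)
  expect_true(out$kept)
  expect_false(out$strand_evaluable)
})

test_that("tightening thresholds never turns a rejected record kept", {
  set.seed(42)
  for (i in 1:200) {
    depth <- sample(10:120, 1)
    alt <- sample(0:depth, 1)
    g_alt <- sample(0:4, 1)
    fwd <- if (alt > 0) sample(0:alt, 1) else 0
    v <- vrec(germline_ref = 100 - g_alt, germline_alt = g_alt,
              tumor_ref = depth - alt, tumor_alt = alt,
              tumor_alt_fwd = fwd, tumor_alt_rev = alt - fwd)
    cfg <- filter_config()
    before <- filter_somatic(v, cfg)
    # perturb every threshold in its strict direction
    tight <- filter_config(
      max_germline_vaf = cfg$max_germline_vaf * runif(1),
      min_tumor_alt_reads = cfg$min_tumor_alt_reads + sample(0:5, 1),
      min_coverage = cfg$min_coverage + sample(0:40, 1),
      min_exomewide_vaf = min(cfg$min_exomewide_vaf + runif(1, 0, 0.3), 1),
      min_strand_reads = cfg$min_strand_reads + sample(0:2, 1),
      max_germline_alt = max(cfg$max_germline_alt - sample(0:1, 1), 0))
    after <- filter_somatic(v, tight)
    if (!before$kept) expect_false(after$kept)
  }
})

test_that("with every rule disabled all records with alt reads pass", {
  off <- filter_config(max_germline_vaf = 1, min_tumor_alt_reads = 0,
                       min_coverage = 0, min_exomewide_vaf = 0,
                       min_strand_reads = 0, max_germline_alt = 1e9)
  set.seed(7)
  for (i in 1:50) {
    alt <- sample(1:50, 1)
    v <- vrec(germline_ref = 50, germline_alt = sample(0:20, 1),
              tumor_ref = sample(0:80, 1), tumor_alt = alt,
              tumor_alt_fwd = 0, tumor_alt_rev = alt)
    expect_true(filter_somatic(v, off)$kept)
  }
})

test_that("shared-position selection relaxes the read-count rule for panel genes", {
  prim <- rbind(
    vrec(pos = 100, gene = "AKAP9", tumor_ref = 37, tumor_alt = 3),
    vrec(pos = 300, gene = "RMG001", tumor_ref = 37, tumor_alt = 3))
  met <- rbind(
    vrec(pos = 100, gene = "AKAP9", tumor_ref = 28, tumor_alt = 12,
         compartment = "metastasis"),
    vrec(pos = 200, gene = "AKAP12", tumor_ref = 25, tumor_alt = 15,
         compartment = "metastasis"))
  rep <- select_shared_positions(prim, met, gene_panel = akap_genes())
  expect_equal(rep$status[rep$pos == 100], "shared")  # alt 3 retained
  expect_equal(rep$primary_alt[rep$pos == 100], 3)
  expect_equal(rep$status[rep$pos == 200], "metastasis_only")
  expect_false(300 %in% rep$pos)                      # non-panel gene
  expect_true(all(rep$tier == "candidate_gene_shared"))

  expect_warning(
    all_g <- select_shared_positions(prim, met, gene_panel = character()),
    "all genes")
  expect_true(300 %in% all_g$pos)
})

test_that("substitution spectrum counts transitions and folds strands", {
  s <- substitution_spectrum(c("A>G", "G>A", "C>T", "A>C"))
  expect_equal(s$transitions, 3)
  expect_equal(s$transversions, 1)
  expect_equal(s$titv_ratio, 3)

  s <- substitution_spectrum(c("A>G"))
  expect_false(s$titv_defined)
  expect_true(is.na(s$titv_ratio))

  s <- substitution_spectrum(c("C>T", "G>A"))
  expect_equal(unname(s$per_substitution_counts["C>T"]), 2L)

  # folding invariance: a set closed under strand complement has the
  # same Ti/Tv as its folded half
  set.seed(1)
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in 1:20) {
    ref <- sample(bases, 30, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    subs <- paste0(ref, ">", alt)
    closed <- c(subs, paste0(comp[ref], ">", comp[alt]))
    expect_equal(substitution_spectrum(closed)$titv_ratio,
                 substitution_spectrum(subs)$titv_ratio)
  }

  # non-SNVs skipped with a count
  s <- substitution_spectrum(data.frame(ref = c("G", "GT"), alt = c("A", "G")))
  expect_equal(s$n_skipped, 1)
})

test_that("pooled t test matches the textbook form and handles degeneracy", {
  expect_equal(pooled_t_test(c(3, 3, 3), c(3, 3, 3))[c("t", "p_value")],
               list(t = 0, p_value = 1))
  r <- pooled_t_test(c(0, 0, 0), c(10, 10, 10))
  expect_equal(r$mean_x, 0)
  expect_equal(r$mean_y, 10)
  expect_equal(r$p_value, 0)

  # oracle: stats::t.test with var.equal = TRUE
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(sample(3:9, 1), sd = 2)
    y <- rnorm(sample(3:9, 1), mean = 1)
    ref <- t.test(x, y, var.equal = TRUE)
    mine <- pooled_t_test(x, y)
    expect_equal(mine$t, unname(ref$statistic))
    expect_equal(mine$p_value, ref$p.value)
  }
})

test_that("mutation load summary compares compartments", {
  cohort <- do.call(rbind, lapply(1:5, function(i) {
    cs <- simulate_case(simulation_params(
      n_snps = 40, somatic_rate_primary = 10,
      somatic_rate_metastasis = 40,   # 4x the primary rate
      sample_id = paste0("P", i), seed = 100 + i))
    rbind(cs$primary_variants, cs$metastasis_variants)
  }))
  res <- mutation_load_summary(cohort)
  means <- setNames(res$group_stats$mean, res$group_stats$compartment)
  expect_gt(means["metastasis"], means["primary"])
  expect_s3_class(res$per_patient, "data.frame")
  expect_equal(nrow(res$per_patient), 5)
  expect_lt(res$test$p_value, 1)

  # single-patient compartment: comparison omitted, counts returned
  one <- cohort[cohort$sample_id == "P1", ]
  res1 <- mutation_load_summary(one)
  expect_null(res1$test)
  expect_equal(nrow(res1$per_patient), 1)
})
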