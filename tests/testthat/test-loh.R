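test_that("major allele frequencies come from tumor counts at germline SNPs", {
  germ <- snps(rep(50, 3), rep(50, 3))
  tum <- snps(c(25, 90, 4), c(25, 10, 3))
  m <- major_allele_frequencies(germ, tum, min_coverage = 10)
  expect_equal(nrow(m), 2)              # 4+3 < 10 dropped
  expect_equal(attr(m, "n_dropped"), 1)
  expect_equal(m$maf, c(0.5, 0.9))
  expect_equal(m$major_allele, c("ref", "ref"))
  expect_true(all(m$maf >= 0.5 & m$maf <= 1))

  tum_alt <- snps(c(10), c(90))
  expect_equal(major_allele_frequencies(germ[1, ], tum_alt)$major_allele,
               "alt")
  expect_warning(
    major_allele_frequencies(germ, snps(50, 50, chrom = "chrZ")),
    "no overlap")
})

test_that("phase concordance test gives exact binomial upper tails", {
  mk <- function(n, k) {
    a <- maf_obs(rep("ref", n))
    b <- maf_obs(c(rep("ref", k), rep("alt", n - k)))
    phase_concordance_test(a, b)
  }
  r <- mk(10, 10)
  expect_equal(r$p_upper, 1 / 1024)
  expect_equal(r$verdict, "concordant_loh")

  r <- mk(10, 8)
  expect_equal(r$p_upper, 56 / 1024)
  expect_equal(r$verdict, "no_loh_evidence")

  r <- mk(10, 0)
  expect_equal(r$p_upper, 1)
  expect_equal(r$verdict, "opposite_allele_loh")

  # ties (maf exactly 0.5) are excluded from n
  a <- maf_obs(rep("ref", 5), maf = c(0.5, 0.9, 0.9, 0.9, 0.9))
  b <- maf_obs(rep("ref", 5), maf = 0.9)
  expect_equal(phase_concordance_test(a, b)$n, 4)

  # symmetry: swapping the samples leaves n and k unchanged
  set.seed(5)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    a <- maf_obs(sample(c("ref", "alt"), n, replace = TRUE),
                 maf = runif(n, 0.5 + 1e-6, 1))
    b <- maf_obs(sample(c("ref", "alt"), n, replace = TRUE),
                 maf = runif(n, 0.5 + 1e-6, 1))
    ab <- phase_concordance_test(a, b)
    ba <- phase_concordance_test(b, a)
    expect_equal(ab$n, ba$n)
    expect_equal(ab$k, ba$k)
  }

  # nothing informative -> not evaluable
  a <- maf_obs("ref", maf = 0.5)
  expect_equal(phase_concordance_test(a, a)$verdict, "not_evaluable")
})

test_that("windowed concordance tracks shared LOH", {
  strong <- maf_obs(rep("ref", 200), maf = 0.95)
  wc <- windowed_concordance(strong, strong, window = 50)
  expect_equal(nrow(wc), 151)
  expect_true(all(wc$verdict == "concordant_loh"))
  expect_false(any(wc$short_window))

  # randomized partner: concordant windows at roughly the 1% nominal
  # rate, the bulk showing no evidence
  set.seed(9)
  rand <- maf_obs(sample(c("ref", "alt"), 500, replace = TRUE), maf = 0.95)
  wc <- windowed_concordance(maf_obs(rep("ref", 500), maf = 0.95), rand,
                             window = 50)
  expect_lt(mean(wc$verdict == "concordant_loh"), 0.05)
  expect_gt(mean(wc$verdict == "no_loh_evidence"), 0.85)

  # window larger than the chromosome -> one flagged shorter window
  wc <- windowed_concordance(strong[1:20, ], strong[1:20, ], window = 50)
  expect_equal(nrow(wc), 1)
  expect_true(wc$short_window)
  expect_equal(wc$n, 20)
})

test_that("mixture fit is refused or flagged on degenerate input", {
  m <- maf_obs(rep("ref", 50), maf = runif(50, 0.5, 1))
  expect_error(fit_loh_mixture(m), "under-determined")
})

test_that("mixture fit recovers a pure heterozygous sample", {
  set.seed(13)
  depth <- 100
  alt <- rbinom(3000, depth, 0.5)
  m <- major_allele_frequencies(snps(rep(50, 3000), rep(50, 3000)),
                                snps(depth - alt, alt))
  fit <- fit_loh_mixture(m, seed = 2)
  expect_lte(fit$pi_loh, 0.05)
  expect_lt(fit$dropout_rate, 0.05)

  # fitted density integrates to 1 on [0.5, 1]
  z <- integrate(function(x) loh_mixture_pdf(fit, x), 0.5, 1,
                 rel.tol = 1e-9, subdivisions = 1000L)
  expect_equal(z$value, 1, tolerance = 1e-6)

  # the kept fit is at least as good as every restart's starting point
  expect_true(all(fit$loglik >= fit$restarts$init_loglik - 1e-8))
})

test_that("purity maps from the beta-component mean", {
  # beta mean 0.95 on the MAF scale -> tumor fraction near 0.9
  set.seed(17)
  n <- 5000
  is_loh <- runif(n) < 0.4
  depth <- 100
  p_alt <- ifelse(is_loh, 0.95, 0.5)
  alt <- rbinom(n, depth, p_alt)
  m <- major_allele_frequencies(snps(rep(50, n), rep(50, n)),
                                snps(depth - alt, alt))
  fit <- fit_loh_mixture(m, seed = 3)
  expect_gte(fit$tumor_fraction, 0.80)
  expect_lte(fit$tumor_fraction, 1.0)
  expect_equal(fit$pi_loh, 0.4, tolerance = 0.1)
  expect_false(fit$degenerate)
})

test_that("artifact LOH fraction measures dropout outside true LOH", {
  m <- maf_obs(rep("ref", 100), maf = 0.55)
  r <- artifact_loh_fraction(m, call_threshold = 0.9)
  expect_equal(r$fraction, 0)

  m$maf <- 0.99
  r <- artifact_loh_fraction(m, call_threshold = 0.9)
  expect_equal(r$fraction, 1)

  # everything inside true LOH -> not evaluable
  r <- artifact_loh_fraction(m, true_loh = region_set("chr1", 0, 1e6),
                             call_threshold = 0.9)
  expect_false(r$evaluable)

  # generator truth: dropout 0.05, no LOH, threshold 0.9
  cs <- simulate_case(simulation_params(n_snps = 5000, dropout_rate = 0.05,
                                        dropout_bias = 0.45, seed = 31))
  m <- major_allele_frequencies(cs$germline, cs$primary)
  est <- artifact_loh_fraction(m, call_threshold = 0.9)
  truth <- truth_report(cs)$realized_dropout$primary_non_loh
  expect_lt(abs(est$fraction - truth), 0.03)
})
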