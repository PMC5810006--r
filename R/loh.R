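#' Major allele frequencies of germline-heterozygous SNPs in a tumor
#'
#' For each heterozygous germline SNP, looks up the tumor counts at the
#' same position and records the major allele frequency
#' `maf = max(ref, alt) / (ref + alt)` (in `[0.5, 1]` by construction)
#' and which allele is major. Positions with tumor coverage below
#' `min_coverage` are dropped and counted in the `n_dropped` attribute.
#'
#' @param germline_het_snps a [snp_table()] restricted to heterozygous
#'   germline calls (used only for its positions).
#' @param tumor a [snp_table()] for the tumor sample.
#' @param min_coverage minimum tumor coverage (inclusive).
#' @return data frame of class `maf_table`: `chrom`, `pos`, `maf`,
#'   `major_allele` (`"ref"`/`"alt"`; `"ref"` on exact ties), `coverage`.
#' @export
major_allele_frequencies <- function(germline_het_snps, tumor,
                                     min_coverage = 10) {
  key_g <- paste(germline_het_snps$chrom, germline_het_snps$pos)
  key_t <- paste(tumor$chrom, tumor$pos)
  ti <- match(key_g, key_t)
  keep <- !is.na(ti)
  if (!any(keep)) warning("no overlap between germline SNPs and tumor")
  ti <- ti[keep]
  cov <- tumor$ref_count[ti] + tumor$alt_count[ti]
  deep <- cov >= min_coverage
  n_dropped <- sum(!deep)
  ti <- ti[deep]; cov <- cov[deep]
  out <- data.frame(
    chrom = tumor$chrom[ti], pos = tumor$pos[ti],
    maf = pmax(tumor$ref_count[ti], tumor$alt_count[ti]) / cov,
    major_allele = ifelse(tumor$alt_count[ti] > tumor$ref_count[ti],
                          "alt", "ref"),
    coverage = cov, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("maf_table", "data.frame")
  attr(out, "n_dropped") <- n_dropped
  out
}

# mixture density on the MAF scale [0.5, 1]:
# (1 - pi) * truncated-normal(mu, sigma on [0.5, 1])
#   + pi * 2 * beta((x - 0.5) / 0.5; a, b)
# exact density (integrates to 1); the likelihood clamps the *data*
# away from the endpoints instead, where dbeta can be infinite
loh_mixture_density <- function(x, pi_loh, mu, sigma, a, b) {
  z <- pnorm(1, mu, sigma) - pnorm(0.5, mu, sigma)
  fn <- dnorm(x, mu, sigma) / z
  fb <- 2 * dbeta((x - 0.5) * 2, a, b)
  (1 - pi_loh) * fn + pi_loh * fb
}

# parameter transforms: unconstrained theta <-> model parameters.
# beta shapes are 1 + m*conc and 1 + (1-m)*conc, keeping both >= 1 so
# the density stays bounded (no endpoint spikes that could swallow the
# heterozygous mass at MAF = 0.5 or blow up the likelihood at MAF = 1)
loh_theta_to_par <- function(theta) {
  list(pi_loh = plogis(theta[1]),
       mu = 0.40 + 0.60 * plogis(theta[2]),
       sigma = 0.001 + 0.499 * plogis(theta[3]),
       m = plogis(theta[4]),                  # beta weight parameter
       conc = exp(theta[5]))                  # beta concentration
}

loh_par_to_theta <- function(pi_loh, mu, sigma, m, conc) {
  c(qlogis(pi_loh),
    qlogis((mu - 0.40) / 0.60),
    qlogis((sigma - 0.001) / 0.499),
    qlogis(m),
    log(conc))
}

loh_beta_shapes <- function(p) {
  list(a = 1 + p$m * p$conc, b = 1 + (1 - p$m) * p$conc)
}

loh_negloglik <- function(theta, x) {
  p <- loh_theta_to_par(theta)
  s <- loh_beta_shapes(p)
  f <- loh_mixture_density(x, p$pi_loh, p$mu, p$sigma, s$a, s$b)
  -sum(log(pmax(f, 1e-300)))
}

#' Fit the Beta-Normal mixture of major allele frequencies
#'
#' Models the MAF distribution of germline-heterozygous SNPs in a tumor
#' as a two-component mixture on `[0.5, 1]`: heterozygous SNPs outside
#' LOH regions follow a normal distribution with mean near 0.5
#' (truncated to the MAF range; the mean drifts upward with allelic
#' dropout), and SNPs inside LOH regions follow a beta distribution
#' (on the MAF linearly rescaled to `[0, 1]`) with mean near 1 that
#' decreases with normal-cell contamination. The mixture weight of the
#' beta component is the estimated LOH fraction of the genome. The
#' log-likelihood is maximized numerically (Nelder-Mead) from
#' `n_restarts` perturbed initializations; the best fit is kept.
#'
#' Derived quantities (package conventions, isolated here):
#' tumor fraction `= clamp(2 * m_beta - 1, 0, 1)` where `m_beta` is the
#' beta-component mean on the MAF scale (copy-neutral LOH has expected
#' MAF `(1 + purity) / 2`), and allelic dropout rate
#' `= clamp(2 * (mu_het - 0.5), 0, 1)`.
#'
#' @param mafs a `maf_table` from [major_allele_frequencies()] (or any
#'   data frame with a `maf` column); at least 200 observations.
#' @param n_restarts number of optimization restarts.
#' @param seed integer seed for the restart perturbations.
#' @return object of class `loh_mixture_fit`: `pi_loh` (=
#'   `loh_fraction`), `mu_het`, `sigma_het`, `beta_a`, `beta_b`,
#'   `tumor_fraction`, `dropout_rate`, `loglik`, `n_snps`, `converged`,
#'   `degenerate` (beta mean below normal mean), and a `restarts`
#'   diagnostics data frame.
#' @examples
#' \donttest{
#' cs <- simulate_case(simulation_params(
#'   n_snps = 2000, purity = 0.9, seed = 1,
#'   loh_regions = region_set("chr1", 0, 1.5e6)))
#' m <- major_allele_frequencies(cs$germline, cs$primary)
#' fit_loh_mixture(m, seed = 1)
#' }
#' @export
fit_loh_mixture <- function(mafs, n_restarts = 8, seed = 1) {
  x <- mafs$maf
  if (length(x) < 200) {
    stop(sprintf(
      "fit refused: %d observations (< 200) make the mixture under-determined",
      length(x)), call. = FALSE)
  }
  if (any(x < 0.5 - 1e-9 | x > 1 + 1e-9)) {
    stop("MAF values must lie in [0.5, 1]", call. = FALSE)
  }
  # keep observations off the endpoints, where the beta density may be
  # unbounded: a MAF of exactly 1 at finite depth carries no more
  # information than "very close to 1"
  x <- pmin(pmax(x, 0.5 + 5e-5), 1 - 5e-5)
  base <- loh_par_to_theta(pi_loh = 0.3, mu = 0.52, sigma = 0.05,
                           m = 0.83, conc = 20)   # beta mean ~0.9 MAF
  fits <- with_local_seed(seed, {
    lapply(seq_len(n_restarts), function(i) {
      theta0 <- if (i == 1) base else base + rnorm(5, sd = 0.75)
      init_nll <- loh_negloglik(theta0, x)
      opt <- tryCatch(
        optim(theta0, loh_negloglik, x = x, method = "Nelder-Mead",
              control = list(maxit = 2000)),
        error = function(e) NULL)
      if (is.null(opt)) {
        list(theta = theta0, nll = init_nll, conv = FALSE,
             init_loglik = -init_nll)
      } else {
        list(theta = opt$par, nll = opt$value, conv = opt$convergence == 0,
             init_loglik = -init_nll)
      }
    })
  })
  nlls <- vapply(fits, `[[`, numeric(1), "nll")
  best <- fits[[which.min(nlls)]]
  p <- loh_theta_to_par(best$theta)
  s <- loh_beta_shapes(p)
  a <- s$a; b <- s$b
  m_beta_maf <- 0.5 + 0.5 * a / (a + b)
  restarts <- data.frame(
    restart = seq_len(n_restarts),
    init_loglik = vapply(fits, `[[`, numeric(1), "init_loglik"),
    loglik = -nlls,
    converged = vapply(fits, `[[`, logical(1), "conv"))
  structure(list(
    pi_loh = p$pi_loh, loh_fraction = p$pi_loh,
    mu_het = p$mu, sigma_het = p$sigma,
    beta_a = a, beta_b = b,
    tumor_fraction = min(max(2 * m_beta_maf - 1, 0), 1),
    dropout_rate = min(max(2 * (p$mu - 0.5), 0), 1),
    loglik = -best$nll, n_snps = length(x),
    converged = best$conv,
    degenerate = m_beta_maf < p$mu,
    restarts = restarts), class = "loh_mixture_fit")
}

#' @export
print.loh_mixture_fit <- function(x, ...) {
  cat("Beta-Normal LOH mixture fit (", x$n_snps, " SNPs)\n", sep = "")
  cat(sprintf("  LOH fraction (pi):  %.3f\n", x$pi_loh))
  cat(sprintf("  tumor fraction:     %.3f\n", x$tumor_fraction))
  cat(sprintf("  dropout rate:       %.3f\n", x$dropout_rate))
  cat(sprintf("  het component:      N(%.4f, %.4f) truncated to [0.5, 1]\n",
              x$mu_het, x$sigma_het))
  cat(sprintf("  LOH component:      Beta(%.2f, %.2f) on rescaled MAF\n",
              x$beta_a, x$beta_b))
  cat(sprintf("  loglik %.2f; converged: %s%s\n", x$loglik, x$converged,
              if (x$degenerate) "; DEGENERATE (beta mean < normal mean)"
              else ""))
  invisible(x)
}

#' Evaluate the fitted mixture density
#' @param fit a `loh_mixture_fit`.
#' @param x MAF values in `[0.5, 1]`.
#' @return density values.
#' @export
loh_mixture_pdf <- function(fit, x) {
  loh_mixture_density(x, fit$pi_loh, fit$mu_het, fit$sigma_het,
                      fit$beta_a, fit$beta_b)
}

#' Binomial SNP-phase concordance test between paired lesions
#'
#' Within a putative LOH region, records the major allele of each
#' germline-heterozygous SNP in sample A (the "phase") and asks whether
#' the major alleles of the corresponding SNPs in sample B agree more
#' often than chance. Under the null of no LOH in B, each position
#' agrees independently with probability 0.5, so the number of
#' concordant calls k among n SNPs is Binomial(n, 0.5); the reported
#' p-value is the upper tail from k to n. A low value (`< 0.01`)
#' indicates the same LOH haplotype in both lesions; a high value
#' (`> 0.99`) indicates LOH of the opposite allele; intermediate values
#' indicate no LOH evidence in B. SNPs with `maf` exactly 0.5 in either
#' sample carry no phase information and are excluded from n.
#'
#' @param region_a,region_b `maf_table`s over the same region, matched
#'   on position.
#' @return list of class `concordance_test`: `n`, `k`, `p_upper`,
#'   `verdict` (`concordant_loh`, `opposite_allele_loh`,
#'   `no_loh_evidence`, or `not_evaluable` when n = 0).
#' @export
phase_concordance_test <- function(region_a, region_b) {
  key_a <- paste(region_a$chrom, region_a$pos)
  key_b <- paste(region_b$chrom, region_b$pos)
  common <- intersect(key_a, key_b)
  ai <- match(common, key_a); bi <- match(common, key_b)
  informative <- region_a$maf[ai] > 0.5 & region_b$maf[bi] > 0.5
  n <- sum(informative)
  if (n == 0) {
    return(structure(list(n = 0L, k = 0L, p_upper = NA_real_,
                          verdict = "not_evaluable"),
                     class = "concordance_test"))
  }
  k <- sum(region_a$major_allele[ai][informative] ==
             region_b$major_allele[bi][informative])
  p_upper <- pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  verdict <- if (p_upper < 0.01) "concordant_loh"
             else if (p_upper > 0.99) "opposite_allele_loh"
             else "no_loh_evidence"
  structure(list(n = as.integer(n), k = as.integer(k),
                 p_upper = p_upper, verdict = verdict),
            class = "concordance_test")
}

#' Moving-window phase-concordance track
#'
#' Applies [phase_concordance_test()] over a moving window of `window`
#' SNPs (step 1) within each chromosome, on the positions shared by the
#' two samples. A chromosome with fewer shared SNPs than `window`
#' yields a single, flagged shorter window.
#'
#' @param sample_a,sample_b `maf_table`s.
#' @param window window size in SNPs.
#' @return data frame: `chrom`, `start_pos`, `end_pos` (1-based span of
#'   the window), `n`, `k`, `p_upper`, `verdict`, `short_window`.
#' @export
windowed_concordance <- function(sample_a, sample_b, window = 50) {
  key_a <- paste(sample_a$chrom, sample_a$pos)
  key_b <- paste(sample_b$chrom, sample_b$pos)
  common <- intersect(key_a, key_b)
  ai <- match(common, key_a); bi <- match(common, key_b)
  a <- sample_a[ai, , drop = FALSE]
  b <- sample_b[bi, , drop = FALSE]
  ord <- order(a$chrom, a$pos)
  a <- a[ord, , drop = FALSE]; b <- b[ord, , drop = FALSE]
  rows <- list()
  for (chr in unique(a$chrom)) {
    ia <- which(a$chrom == chr)
    n_chr <- length(ia)
    starts <- if (n_chr < window) 1L else seq_len(n_chr - window + 1L)
    w <- min(window, n_chr)
    for (s in starts) {
      sel <- ia[s:(s + w - 1)]
      ct <- phase_concordance_test(a[sel, , drop = FALSE],
                                   b[sel, , drop = FALSE])
      rows[[length(rows) + 1]] <- data.frame(
        chrom = chr, start_pos = a$pos[sel[1]], end_pos = a$pos[sel[w]],
        n = ct$n, k = ct$k, p_upper = ct$p_upper, verdict = ct$verdict,
        short_window = w < window, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Artifact-LOH (false negative / allelic dropout) fraction
#'
#' Measures the fraction of LOH calls in regions without true LOH, as
#' an estimate of the allelic-dropout artifact rate: amplification bias
#' mimics LOH outside genuinely affected regions. A SNP counts as
#' LOH-called when it lies inside `loh_calls` (if supplied) or when its
#' `maf >= call_threshold`.
#'
#' @param snps a `maf_table`.
#' @param true_loh a [region_set()] of regions with true LOH (may be
#'   empty).
#' @param call_threshold MAF at or above which a SNP counts as an LOH
#'   call (used when `loh_calls` is `NULL`).
#' @param loh_calls optional [region_set()] of called LOH positions.
#' @return list: `fraction` (called / all, over SNPs outside
#'   `true_loh`; `NA` with `evaluable = FALSE` when no SNP lies outside
#'   `true_loh`), `n_outside`, `n_called_outside`, `evaluable`.
#' @export
artifact_loh_fraction <- function(snps, true_loh = region_set(),
                                  call_threshold = 0.9,
                                  loh_calls = NULL) {
  outside <- !in_regions(snps$chrom, snps$pos, true_loh)
  if (!any(outside)) {
    return(list(fraction = NA_real_, n_outside = 0L,
                n_called_outside = 0L, evaluable = FALSE))
  }
  called <- if (is.null(loh_calls)) snps$maf >= call_threshold
            else in_regions(snps$chrom, snps$pos, loh_calls)
  list(fraction = sum(called & outside) / sum(outside),
       n_outside = sum(outside),
       n_called_outside = sum(called & outside),
       evaluable = TRUE)
}

# run code with a temporary RNG state seeded by `seed`
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
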