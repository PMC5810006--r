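---
title: "Methods: models and design choices in pairedmet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models and design choices in pairedmet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairedmet)
```

pairedmet implements the downstream arithmetic of a paired
primary/metastasis tumor-exome analysis: everything that happens *after*
alignment and variant calling. Callers such as VarScan or Mutect, and
all wet-lab steps, are out of scope; the package consumes their tabular
output. This vignette explains each model, its assumptions, the
tunables, and the choices we made where the design was genuinely open.

## Somatic filtering

A candidate call is kept exome-wide when **all** of the following hold
(defaults in `filter_config()`):

* germline VAF strictly below 1% (`max_germline_vaf = 0.01`);
* at least 5 tumor alternate reads (`min_tumor_alt_reads = 5`);
* tumor coverage strictly above 30 (`min_coverage = 30`);
* tumor VAF strictly above 16% (`min_exomewide_vaf = 0.16`);
* no QC flag fires.

The strict inequalities ("> 30", "> 16%") are deliberate: we read the
published thresholds as printed. The coverage rule is applied to the
*tumor* sample; whether it was meant for tumor, germline or both is not
documented in the source pipeline, so this interpretation is a stated
choice rather than a reconstruction.

The original workflow also removed positions after a manual IGV review
("variant reads in the normal sample, poor alignment, variant reads in
one direction only"). Visual alignment review cannot be reproduced
programmatically; we replace it with two computable proxies and do not
claim to emulate the rest:

* `normal_support` — more than `max_germline_alt` (default 1) germline
  alternate reads, even when the germline VAF rule passes;
* `single_strand` — fewer than `min_strand_reads` alternate reads on
  either strand. When strand counts are absent the rule reports "not
  evaluable" instead of passing or failing (`strand_evaluable` column).

`select_shared_positions()` implements the candidate-gene relaxation:
for genes on a panel, a position seen in either lesion is retained even
below the alt-read/VAF thresholds — provided germline, coverage and QC
rules still hold — so that true shared low-frequency mutations are not
discarded. Positions are matched on `(chrom, pos, ref, alt)`:
substitution identity, not just locus.

`pooled_t_test()` is the classic equal-variance two-sample t;
degenerate zero-variance input returns t = 0, p = 1 for equal means
rather than an error, because simulated count vectors can legitimately
be constant.

## CNV track

`log2_ratio_track()` computes, per SNP,
$\log_2\!\big((t_i/T)\,/\,(g_i/G)\big)$ where $t_i, g_i$ are tumor and
germline coverages and $T, G$ their totals, then recenters the track to
zero. "Recentering" is median subtraction by default: the median is
robust when a large fraction of the genome is copy-altered, which is
common in these tumors; mean-centering is available via `center =
"mean"`. Smoothing (`moving_average()`) uses a *centered* window of 10
adjacent SNPs — the source describes only "a moving average across ten
adjacent SNPs", so the alignment is our choice, with a trailing window
available (`align = "right"`). Windows and runs never cross chromosome
boundaries; chromosome ends use the shorter available window.

Segment calling (`call_segments()`) thresholds the smoothed track at
±0.3 with a minimum run of 10 SNPs, merging same-call runs separated by
a single SNP. These cutoffs are *package defaults, not published
values* — the source reports per-locus deletion/amplification calls but
no numeric rule — and are exposed in `pipeline_config()`.

## LOH: the Beta-Normal mixture

For heterozygous germline SNPs, the tumor major allele frequency
$\mathrm{MAF} = \max(r, a)/(r + a) \in [0.5, 1]$ is bimodal when the
genome contains LOH:

* **het component** — SNPs outside LOH: a normal
  $\mathcal N(\mu, \sigma)$ truncated to $[0.5, 1]$, mean near 0.5 in a
  clean sample, drifting upward with allelic dropout;
* **LOH component** — a beta distribution on the MAF rescaled linearly
  to $[0, 1]$, mean near 1, pulled down by normal-cell contamination.

The mixture weight $\pi$ of the beta component **is** the estimated LOH
fraction. The likelihood is maximized numerically (Nelder-Mead on
transformed parameters) from 8 seeded restarts; initialization
$\pi = 0.3$, $\mu = 0.52$, $\sigma = 0.05$, beta mean $\approx 0.9$ on
the MAF scale, concentration 20, perturbed per restart. The kept fit's
log-likelihood is never below any restart's starting value, and fits on
fewer than 200 SNPs are refused as under-determined.

Numerical choices worth knowing:

* The beta shapes are parameterized as $a = 1 + m\,c$,
  $b = 1 + (1 - m)\,c$, keeping both $\ge 1$. This keeps the density
  bounded — otherwise a shape below 1 puts an integrable spike at an
  endpoint that can swallow the heterozygous mass at MAF = 0.5 or chase
  individual observations at MAF = 1, and the "density" seen by
  diagnostics would not integrate to 1.
* Observations are clamped $5\times10^{-5}$ away from the endpoints
  before likelihood evaluation: a MAF of exactly 1 at finite depth
  carries no more information than "very close to 1".
* Whether the original fit truncated its components is unknowable from
  the source; truncation of the normal to the observable range is our
  choice and is what makes the fitted object a proper density on
  $[0.5, 1]$ (verified by quadrature in the tests).

**Derived quantities.** The source states that tumor fraction and
dropout are "estimated from the fit" without formulas. Our mappings,
isolated in one place and to be read as package conventions:

* tumor fraction $\hat\rho = \mathrm{clamp}(2 m_\beta - 1,\, 0,\, 1)$,
  where $m_\beta$ is the beta mean on the MAF scale — under copy-neutral
  LOH at purity $\rho$ the retained allele's expected MAF is
  $(1+\rho)/2$;
* dropout rate $= \mathrm{clamp}(2(\mu - 0.5),\, 0,\, 1)$ — the het
  component's upward drift rescaled to a fraction.

A fit whose beta mean falls below the normal mean is flagged
`degenerate` and its $\pi$ should not be trusted.

Note one behavior that mirrors the real data: WGA allelic dropout
pushes het SNPs toward MAF 1, so with dropout present the fitted $\pi$
absorbs dropout SNPs and overestimates the true LOH fraction — exactly
the artifact the false-negative control analysis quantifies.
`artifact_loh_fraction()` measures it directly as the fraction of
LOH-like calls (MAF at or above a threshold, default 0.9) outside
regions of true LOH.

## SNP-phase concordance

Within an LOH region of sample A, each SNP's major allele defines a
phase. Under the null of no LOH in sample B, B's major alleles are coin
flips relative to A, so the number of concordant calls $k$ among $n$ is
Binomial($n$, 0.5) and the reported p-value is the upper tail
$\sum_{i=k}^{n} \binom{n}{i} 2^{-n}$ — implemented exactly and verified
against brute-force enumeration of all $2^n$ outcomes for $n \le 16$.
Verdicts use the worked interpretation from the source: $p < 0.01$ —
same-haplotype LOH in both lesions; $p > 0.99$ — LOH of the *opposite*
allele; otherwise no LOH evidence in B. Ties (MAF exactly 0.5) carry no
phase and are excluded from $n$ deterministically rather than broken at
random. `windowed_concordance()` slides a 50-SNP window (step 1) within
each chromosome.

## Enrichment summaries

`fisher_family_enrichment()` computes the two-sided Fisher exact
p-value by probability ordering (summing hypergeometric probabilities
of tables no more probable than the observed one) — the most common
convention, and the one `stats::fisher.test` uses, which the tests
exploit as a second oracle next to direct enumeration. The published
"p < 0.02" enrichment does not document how its 2×2 was built
(mutation-level vs patient-level), so the function takes an explicit
table and the pipeline reports the mutation-level construction; any
alternative can be fed in directly.

Presence of a mutation in a lesion means VAF strictly above 0 by
default, matching tables that print absence as "0%"; cells holding two
VAFs from multiple blocks of one sample are kept as lists and
summarized by their maximum — the source reports both values without an
aggregation rule, and the maximum preserves "detected at this level in
at least one block". Missing (not assayed) cells never count as
presence. Trajectories are ordered primary → axillary → metastasis 1 →
metastasis 2 and called monotone non-strictly over non-missing entries.

The Table 5 fixture deserves a caveat: the printed CNV table interleaves
per-patient cells with cohort-2 count columns ambiguously. The fixture
encodes only the cells that the accompanying prose states unambiguously
(AKAP1, AKAP7, AKAP8, AKAP11, AKAP12) plus the cohort-2 counts restated
in prose; the lone deletion cells for AKAP5 and AKAP6 cannot be
assigned to a patient and are omitted from the per-patient calls (the
loci remain in the locus set). Locus windows are approximate, anchored
on the mutation coordinates and megabase positions the text itself
gives.

## The simulator: a stated world

`simulate_case()` draws the data-generating process every estimator
assumes, with ground truth recorded for recovery tests:

* het SNPs: alternate reads Binomial(depth, 0.5), depth Poisson;
* copy-neutral LOH: one retained haplotype per region (shared between
  primary and metastasis — the phase-concordance signal), retained
  allele fraction $(1+\rho)/2$;
* dropout: with probability $d$ per SNP and compartment, reads are
  resampled at $0.5 \pm$ `dropout_bias` (default 0.45, i.e. a strong
  bias mimicking near-complete allelic loss during WGA);
* CNV: depth scaled by copy_number/2 inside segments;
* somatic mutations: Poisson counts split into shared / primary-only /
  metastasis-only, genes drawn from a 505-symbol universe (the real
  recurrent-gene list is unpublished, so 491 synthetic symbols back the
  14 AKAPs), with family genes upweighted in the metastasis by the
  enrichment multiplier.

Defaults state the world of the study rather than tuning knobs: purity
0.8, depth 100×, dropout 5% (the published metastasis false-negative
fractions average ~4.9%), 6 vs 24 expected recurrent-gene mutations in
primary vs metastasis (the published per-patient averages), shared
fraction 0.2. Copy-neutral LOH was chosen as the simulated mechanism
because deletion-LOH would couple the LOH and CNV truths and blur which
estimator is being tested.

What the generator does **not** emulate: mapping artifacts, FFPE
damage, GC-dependent coverage waves, subclonal structure beyond a
uniform clonality draw, linked haplotypes beyond the per-region
retained allele. A green recovery test therefore establishes
correctness of the estimators *under the stated model*, not robustness
to every failure mode of real exomes.

## Orchestration

`run_pipeline()` chains filter → CNV → LOH fit → phase test →
enrichment, writing TSV/JSON per stage plus a manifest (config, seed,
package version, timestamp). Reruns under the same seed are
byte-identical apart from the manifest timestamp. The `pairedmet`
script under `inst/exec/` exposes the same stages as subcommands with
exit codes 0 (success), 2 (validation error), 3 (stage failure).

## Known limitations

* The purity/dropout mappings are assumptions, not reconstructions; on
  real data with segmental aneuploidy the copy-neutral mapping biases
  $\hat\rho$.
* No LOH segmentation is provided beyond thresholding and the
  concordance track; region boundaries were called manually in the
  source study.
* The Fisher construction of the published enrichment p-value is not
  uniquely recoverable; we expose the machinery rather than assert one
  table.
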