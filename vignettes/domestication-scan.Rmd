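---
title: "Farmed-versus-wild differentiation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Farmed-versus-wild differentiation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`domescan` analyses domestication signatures in farmed versus wild fish
populations on two scales: individual candidate-gene genotypes and pooled
whole-genome base counts. This vignette records the models behind each
stage, the parameters that matter, what the synthetic-data generator does
and does not emulate, and the design decisions taken where several
reasonable options existed.

## The gene-level model

Each population contributes `n` diploid individuals genotyped at one or a
few SNPs. Analyses treat the **population, not the individual, as the
sampling unit**: the Wilcoxon rank-sum test compares the per-population
variant-allele frequencies of farmed versus wild groups (matching how such
data are displayed, one box per group of population values), and the GLM
models per-population binomial allele counts.

* **Wilcoxon** (`wilcoxon_origin_test()`): two-sided. For a combined
  sample of at most 12 populations the permutation distribution of the
  midrank sum is enumerated exactly and the p-value is `2·min(tails)`
  capped at 1; ties are handled by midranks inside the enumeration rather
  than by switching to an approximation, because the frequency values of
  small populations tie frequently and the approximation is noticeably
  anticonservative at these sizes (for three identical values per group it
  gives 0.047 where the exact answer is 0.1). Larger samples use the
  normal approximation with tie correction and continuity correction.
* **Hardy–Weinberg** (`hwe_test()`): the default is the exact conditional
  test (probabilities of all heterozygote counts given the allele counts);
  population samples of 2–10 individuals make the chi-square approximation
  unreliable, though it is available via `method = "chisq"`.
* **GLM and model selection** (`fit_origin_time_glm()`,
  `stepwise_aic()`): binomial logit fit of `cbind(ref, alt)` per
  population on `origin` (farmed/wild) and `time` (the binary 2004–2007
  versus 2012–2016 collection-period split), with the reference allele
  defined as the most frequent allele in the farmed populations (ties
  broken lexicographically and logged). AIC is `−2·logLik + 2·npar`.
  Stepwise selection runs in both directions from the full `origin*time`
  model over the lattice `{1, origin, time, origin+time, origin*time}`,
  respecting marginality; AIC ties go to the smaller model. The search
  agrees with `MASS::stepAIC` on every dataset we have tested. Note that
  a multi-step search retains a spurious factor more often than the 15.7%
  of a single AIC comparison; under a pure null the intercept-only model
  is the modal but not a near-certain outcome (~45–50% of replicates).
  Quasi-separation is flagged (`separation = TRUE`) but the fit is still
  returned.

## The bottleneck null

Farmed stocks of both motivating species derive from wild populations
through a documented contraction to roughly 100 effective breeders some
5–10 generations ago. Pure drift through that bottleneck can move allele
frequencies far enough to fool any farmed-versus-wild test, so gene-level
significance is benchmarked against a Wright–Fisher null
(`bottleneck_fpr()`):

1. start from the observed wild frequency `p0`;
2. resample `2·nb` chromosomes binomially for `G` generations
   (`wf_trajectory()`; defaults `nb = 100`, `G = 8`, the midpoint of the
   documented 5–10);
3. draw a farmed sample of `2·n_farmed` alleles at the drifted frequency
   and a wild sample of `2·n_wild` alleles at `p0` (sample sizes default
   to the empirical 37 farmed / 54 wild design);
4. apply the Fisher exact test; the FPR at level α is the fraction of
   replicates with `p < α`.

Design choices: the demography is an instantaneous drop to `nb` (the
pre-bottleneck size of 10⁴–10⁶ contributes per-generation variance of at
most 1/(2·10⁴) and is not simulated); the test contrasts the simulated
farmed sample with a freshly drawn wild sample by default
(`wild_sampling = "expected"` fixes the wild table instead); the test unit
is the allele-count 2×2 table. With no drift (`generations = 0`) the FPR
stays at or below the nominal level because the exact test is
conservative under discreteness; 8 generations at `nb = 100` inflate it
severalfold — around 20% at α = 0.05 and a few percent at α = 0.01 for
intermediate frequencies, which is why a 1% threshold is the robust choice
for calling gene-level differences.

## Depth calibration for pooled genotyping

A pooled library only represents an individual if at least one read at the
site came from it. `distinct_individuals()` resamples read identities
uniformly over the `P` pool members: the mean number represented follows
the closed form `P·(1 − (1 − 1/P)^D)` (15.99 for `P = D = 25`), and the
reported lower bound is the 2.5% quantile of the simulated distribution
(a two-sided 95% interval; the one-sided 5% quantile is available with
`side = "one"`). For a pool of 25 at depth 25, at least 13 of the 25
individuals — half of all genotypes — are represented at the lower bound,
which is the rationale for the depth-25 site filter.
`choose_min_depth()` searches depths upward for the smallest one meeting a
target fraction; for `P = 25` and target one half it settles on 24–25
(the bound sits exactly at the 13-individual threshold there, so
Monte-Carlo replicates straddle the two depths; the filter uses the
conservative 25). "Samples" are interpreted as diploid individuals, not
chromosomes, and equal DNA contribution per individual is assumed.

## Pool-Seq calling and scan statistics

Input is per-position base counts per library in either a
bam-readcount-style layout (`chrom pos ref depth base:count[:...]`) or the
PoPoolation2 sync format (`A:T:C:G:N:del` per pool), 1-based inclusive
coordinates throughout. Technical replicates are merged by summing counts
(`merge_replicates()`, an outer join on position that errors on reference
mismatches). `call_biallelic()` then:

1. drops a site if **any** pool is below `min_depth` (default 25) — the
   downstream pairwise statistics need every pool covered; a masking mode
   (`depth_rule = "mask"`) keeps the site and masks only the under-covered
   pools;
2. computes base frequencies from counts summed across all pools (the
   cross-pool default; `maf_scope = "per_pool"` instead retains a base
   reaching the cutoff in at least one pool) and discards bases below
   `min_maf` (default 1%) as likely sequencing error;
3. emits the site iff exactly two bases remain, the more frequent one as
   major (ties alphabetical, logged). `N` and indel counts never enter
   calling.

Per SNP, `scan_statistics()` reports the combined-pool FST (headline), the
mean over all farmed × wild pairwise FSTs, Fisher's exact p on the
combined table, and the CMH chi-square over pool-pair strata (by default
the i-th farmed pool is paired with the i-th wild pool after sorting pool
ids; an explicit pairing table is accepted). BH adjustment is applied per
chromosome.

Numerical notes:

* The pooled FST estimator carries the finite-depth correction `C/(C−1)`
  in both `π_T` and the within-pool values; because `π_T` is computed at
  the combined depth, the corrections do not cancel for identical pools
  and FST has a small negative bias of order `1/(2C)`. Negative estimates
  are reported as computed (`clamp_fst = TRUE` clamps for plotting); a
  fixed difference gives exactly 1.
* The CMH continuity correction (on by default) subtracts 0.5 from the
  summed deviation only when that deviation reaches 0.5, matching
  `stats::mantelhaen.test`, so the correction can never overshoot zero.
* The Fisher implementation is vectorised over sites and reproduces
  `stats::fisher.test` (two-sided by summing hypergeometric probabilities
  not exceeding the observed table's, with the same 1e-7 relative
  tolerance).
* Fisher and CMH treat reads as independent draws of alleles. With finite
  pools this is optimistic: the pool's `2n` chromosomes are themselves a
  sample, so combined read counts are overdispersed relative to the
  binomial null and a naive per-SNP test rejects more than its nominal
  level even without any farmed–wild divergence. This is a known property
  of read-level Pool-Seq tests, it is visible in our drift-null
  simulations, and it is the second reason (besides the bottleneck) why
  single-SNP significance is never interpreted without the region-level
  track and a null calibration.

## Rolling track, peaks, genes

`rolling_track()` computes a centred moving mean over a window of SNPs (by
SNP index, not bp), skipping masked values and truncating at the edges;
`find_peaks()` takes the global maximum of the track and, within that
window, reports the SNP with the maximum per-SNP statistic and its
BH-adjusted significance — the value displayed at scan peaks.
`genes_near()` returns annotated genes within `flank` bp (default 50,000)
on each side of a position, i.e. a 100-kbp total window.

**Window scale.** The published analysis used a 5000-SNP window over
chromosomes carrying 300–600k SNPs, i.e. roughly 1% of the chromosome.
That ratio, not the absolute 5000, is what transfers to other problem
sizes: with edge truncation, a window comparable to the chromosome length
biases the track maximum toward the edges (truncated windows divide the
same signal contribution by a smaller count), and the argmax degenerates
into a wide plateau. The package default remains 5000 for full-scale data;
the desk-scale analyses and tests (≈10⁴ surviving SNPs) use a 251-SNP
window, the same ~2.5% relative scale, which recovers an injected 500-SNP
selected region in 20/20 seeded runs.

## The synthetic-data generator

`simulate_poolseq()` emulates, per SNP: a wild variant frequency from a
Beta(0.8, 0.8) prior (a U-shaped spectrum typical of genome-wide SNPs; the
motivating study does not report its spectrum, so this is a stand-in, not
an inference); a farmed frequency produced either by one shared
Wright–Fisher bottleneck pass (`farmed_null = "drift"`, the default, so
the null carries realistic drift noise common to all farmed pools) or
copied exactly (`"identical"`, for clean-null experiments); inside an
optional `selected_region`, a shift of the farmed frequency by Δ away
from the wild value (toward the more distant boundary, so the true
divergence is exactly Δ). Each pool then draws `2n` chromosomes
binomially, a read depth from a negative binomial (mean 60, dispersion 5
by default — overdispersion mimicking real Pool-Seq coverage), and variant
reads binomially at the pool frequency; technical replicates partition the
pool's reads, so replicate depths sum exactly. SNP positions are uniform
without replacement; gene models are uniform intervals written as minimal
GFF3.

Not emulated: read-level artefacts (sequencing error, mapping bias),
linkage disequilibrium between SNPs, unequal DNA contribution of pool
members, and population structure among pools of the same origin. Passing
tests on these simulations therefore demonstrate the statistical machinery
and its calibration, not robustness to those real-data complications.

`simulate_genotypes()` draws Hardy–Weinberg genotypes per population from
the design's sample sizes; farmed populations either share a fixed
frequency or receive independent drifted frequencies.

## Problem sizes used in tests and analyses

The shipped analyses and the acceptance checks run at desk scale, chosen
so the full suite completes in minutes while keeping every Monte-Carlo
bound comfortably away from its tolerance: 20,000 simulated SNPs per
chromosome (≈10⁴ after filters) with 4 farmed + 4 wild pools of 25 at mean
depth 60; 10³ bottleneck replicates per configuration (2 × 10³ in the
calibration checks); 10⁵–10⁶ resampling replicates for the depth
calibration; 20 seeded scan repetitions for the recovery rate. The
depth-calibration workflow keeps the published 10⁶ replicates since it
runs in seconds.

## Known limitations

* The per-SNP tests inherit the read-level independence assumption
  discussed above; their p-values rank sites well but are not calibrated
  error probabilities for finite pools.
* The bottleneck null treats loci independently (no linkage) and ignores
  mutation, migration and selection during the bottleneck.
* BH adjustment is applied per chromosome, matching the per-chromosome
  scan design; genome-wide error control across chromosomes would need a
  joint adjustment.
* The exact Wilcoxon enumeration is limited to 12 populations combined;
  beyond that the tie-corrected normal approximation is used.
* `bottleneck_fpr()` reports the FPR of the *Fisher* test under drift;
  the GLM and Wilcoxon FPRs under the same null can be obtained by
  simulating genotype tables with `simulate_genotypes(farmed_freq =
  "drift")` and re-running the track, at higher cost.
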