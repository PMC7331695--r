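---
title: "Copy-number liquid biopsy profiling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number liquid biopsy profiling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liquidSCNA)
```

## What the package models

Circulating tumor cells (CTCs) captured from a blood draw yield a few cells'
worth of DNA. After whole-genome amplification (WGA) and low-coverage
sequencing (on the order of a million reads per sample, ~0.02x coverage),
point mutations are unreliable but somatic copy number alterations (SCNAs) —
chromosome-, arm- and cytoband-scale gains and losses — leave a robust,
reproducible signal in binned read counts. liquidSCNA implements the
computational chain that turns such counts into biology:

1. **Bin profiling** — normalize binned counts, remove smooth GC/mappability
   amplification bias by loess, segment by circular binary segmentation
   (CBS), and scale segments to integer copy states via a ploidy fit.
2. **SCNA calls** — collapse bins to gene- and cytoband-level log2 values
   and ternary gain/neutral/loss calls, optionally restricted to a focus
   panel of recurrently altered loci.
3. **Concordance** — quantify how faithfully a CTC reproduces its matched
   tumor: sensitivity, specificity, shared-alteration fraction,
   correlations, and complete-linkage/Euclidean clustering with pair
   co-membership.
4. **Tissue-of-origin classification** — a random forest over whitelisted
   cytoband values plus a chromosomal instability (CIN) score and two t-SNE
   embedding coordinates, with type elimination and class grouping.
5. **Synthetic data** — seeded generators for genomes, clonally related
   tumor/CTC state profiles, GC-biased overdispersed read counts and
   multi-class SCNA cohorts, so that every stage is testable end to end
   without any external download.

All genomic coordinates are 0-based half-open (BED convention).

## The read-count model

For bin $i$ with copy state $s_i$, length $\ell_i$, mappability $m_i$ and GC
fraction $g_i$, expected reads are

$$\mu_i \propto s_i\,\ell_i\,m_i\,\exp\{-c\,(g_i - g_0)^2\},$$

normalized to the sample's total read count. The multiplicative
log-quadratic GC term (peak $g_0 = 0.45$, curvature $c = 10$ by default) is
the unimodal amplification bias that loess correction is designed to
remove. Counts are Poisson when `dispersion = 0`; otherwise they are
negative binomial via a Gamma-distributed per-bin amplification factor whose
coefficient of variation is the `dispersion` parameter, i.e.
$\mathrm{Var} = \mu + (d\,\mu)^2$. The default $d = 0.3$ (30% amplification
noise per 250-kb bin) sits inside the range reported for
multiple-displacement amplification of few-cell input. We model smooth bias
plus overdispersion only; locus dropout is deliberately out of scope, since
the correction stage removes smooth bias and nothing else.

The default study conditions used by the demo pipeline and the package's
own end-to-end checks are: a six-chromosome, 300-Mb genome tiled by 250-kb
bins (1,200 bins — a desk-scale stand-in for a genome that keeps a full
hundred-seed experiment inside a few minutes), $10^6$ reads per sample
(matching the ~0.9 M uniquely mapped reads a low-pass CTC library
yields, with 0.5 M as the downsampling point), ten tumor events of 20–40
bins with states in {0, 1, 3, 4, 5, 6}, and dispersion 0.3.

## Bias correction

`correct_bias()` fits `loess(ratio ~ gc, span = 0.3, degree = 2,
family = "symmetric")`, divides the fit out, optionally repeats for
mappability, and re-centers to mean 1. Two safeguards keep copy-number
signal out of the bias estimate. The curve is fitted on copy-neutral-ish
bins only — ratios within \[0.7, 1.3\] of the median — and then applied to
all bins (covariate clamped to the fitted range): several altered segments
concentrated in one GC range would otherwise pull the curve toward
themselves and have their amplitude divided away. The symmetric family
additionally downweights vertical outliers inside the fitting set. The
fitted curve is floor-clamped (default 0.05) so sparse GC extremes cannot
blow up the division, and a constant GC vector is reported and skipped —
there is nothing to fit.

## Segmentation

CBS is run per chromosome on $\log_2(\text{ratio} + 10^{-3})$: the maximal
circular-arc mean-shift statistic is tested against `nperm = 1000`
permutations; arcs with $p \le \alpha = 0.01$ split the interval and the
recursion continues on the parts (`min_width = 3` bins). These are
conventional CBS defaults; the permutation loop early-exits once the
exceedance count proves $p > \alpha$, which changes no decision. Adjacent
segments with numerically equal means are merged. On noiseless input the
procedure returns exactly one segment per chromosome, and on 30-bin tracks
its breakpoints coincide with an exhaustive least-squares dynamic
programming oracle in ≥95% of seeded trials (the test suite checks both).

## Ploidy and integer states

Segment ratios are relative; absolute states need a multiplier $p$ such
that $r_i\,p$ is near-integer. Scaling from ratios alone is degenerate in
both directions: any solution is reproduced exactly by its double (twice an
integer is an integer), while a spuriously dense high-ploidy lattice can
fit noisy segment means *better than chance* by snapping them to nearby
integers. `fit_ploidy()` therefore proceeds in stages. Stage zero excludes
structurally wrong candidates: any multiplier that leaves more than ~an
arm's worth of wide-segment mass (120 bins) as capped standardized
outliers — an accidental sub-lattice can win a raw score photo-finish
while stranding the entire copy-neutral baseline. Then a grid
scan over $p \in [1.5, 6]$ (step 0.05) minimizes a weighted,
outlier-capped distance to the integer lattice, with weights
$1/\max(r, 0.25)^2$ — read noise is multiplicative, so ratio variance
scales with the ratio squared — and per-bin contributions capped at 0.25,
because segments straddling true breakpoints are model outliers; ties
resolve toward the smallest candidate, and the state-space residual
scaling deliberately biases near-ties toward the smallest plausible
ploidy (the parsimony convention). Second, a *reduction guard* tests the
plausible down-scalings $p/2$, $2p/3$, $3p/4$ using segment-level
standardized residuals ($z_k$ with $sd_k = m_k\,\hat{c}_v/\sqrt{L_k}$,
$\hat{c}_v$ estimated robustly from within-segment residuals): the fit
moves to the smallest reduction that strands no more than one breakpoint
mixture's worth of genomic mass (40 bins in wide capped segments) and
keeps the capped $\chi^2$ within a generous band — this rescues the
occasional profile whose noisy means selected a multiple of the true
scaling, without ever halving a genuine tetraploid whose odd states cover
arm-scale stretches. Third, inverse-variance weighted least squares on the
inlier segments moves the estimate off the grid without leaving its basin.

Two consequences are worth knowing. First, a tetraploid baseline is
recovered (the tests include a baseline-4 clone with arm-scale events at
states 3 and 6, recovered within ±0.1) only when odd copy states cover an
arm-scale stretch of the genome; a tetraploid whose only odd-state evidence
is one short focal event is genuinely unidentifiable and resolves to the
parsimonious scaling. Second, gene-level values are expressed relative to
the sample's *modal* integer state rather than the rounded ploidy — with
ten events the genome-wide mean state often sits near a half-integer, and
rounding it would flip the entire baseline of an otherwise clean profile.

## Gene and cytoband values, calls

A gene's value is the overlap-length-weighted mean of
$\log_2(\text{segment ratio} \times p / \text{baseline})$ over the bins it
intersects, clamped to ±3 so that homozygous deletions (otherwise
$\log_2 \varepsilon \approx -10$) cannot dominate distances and
correlations downstream. Strand is ignored; copy number is strandless.
Cytobands take the unweighted mean of member genes, membership by gene
midpoint so a boundary-spanning gene is counted once. Ternary calls use a
strict threshold, default $\tau = 0.3$ on the log2 scale — a GISTIC-like
low-level cut; the underlying study reports gains and losses without
stating its threshold, so $\tau$ is an explicit, configurable parameter. A
value exactly at $\tau$ is neutral.

## Concordance statistics

Two related but distinct statistics are reported, because the loose term
"concordance" conflates them: **sensitivity** (tumor-altered features whose
CTC call has the same sign, over tumor-altered features) and the stricter
**shared fraction** (same-sign agreement over the union of features altered
in either sample — private CTC events count against it). Specificity is
neutral-in-both over tumor-neutral. Ratios with zero denominators are
reported missing, never 0. Clustering uses complete linkage on Euclidean
distances; a CTC–tumor pair "co-clusters" when the dendrogram joins the two
samples before either joins anything else — a deliberately strict,
merge-order-based reading of pair co-membership.

With the default demo design (shared fraction 0.9 at event level plus one
private CTC event per patient), the expected gene-level shared fraction
over the union is about $0.9 \times 10/11 \approx 0.82$ before measurement
noise; the demo's observed values (~0.75 mean shared, ~0.84 median
sensitivity, ~0.95 specificity, 9/9 co-clustering) are the package's own
numbers under its own synthetic conditions, not a reproduction of any
clinical dataset.

## The tissue-of-origin model

`build_features()` restricts a cytoband matrix to a whitelist of
cancer-associated cytobands (the whitelist length is configurable — the
feature-reduction step of the underlying protocol is reported with slightly
different counts in different places, so no single number is hard-coded),
then appends the CIN score — the *sum* of absolute SCNA values, missing as
0, which makes CIN additive over disjoint whitelists — and two t-SNE
coordinates computed on the z-scored whitelisted values (exact t-SNE,
perplexity 30, 1,000 iterations, seeded).

Training follows a two-pass protocol: pass 1 fits a 500-tree random forest
on the raw tumor types (stratified 80/20 split; the mtry grid
$\{\sqrt{p}, p/4, p/2\}$ is tuned by 5-fold × 3-repeat stratified CV on the
training split only) and eliminates types whose out-of-bag balanced
accuracy falls below 0.5 — "balanced" as the mean of a type's sensitivity
and specificity, robust to class imbalance. Pass 2 maps survivors through a
class-grouping table, refits, and reports overall accuracy plus per-class
balanced accuracy on the held-out test samples. Class imbalance is handled
by stratification only, with no resampling.

New samples (the CTC case) cannot be dropped into a finished t-SNE without
either leaking or destroying determinism, so out-of-sample coordinates are
interpolated: the inverse-distance-weighted mean of the k = 15 nearest
training samples' coordinates in z-scored feature space, with a
zero-distance match returning that sample's coordinates exactly.
Classification refuses to run when fewer than 80% of the model's cytobands
are present, and imputes (with a warning) the remainder as 0.

## What the generators emulate — and what they do not

The synthetic cohorts give each class a signature of recurrent cytoband
events (span, direction, prevalence, amplitude), Poisson-rate passenger
events and Gaussian background noise. This reproduces the *structure* the
classifier consumes — class-specific recurrent SCNAs over a cytoband
universe — but real pan-cancer data differ in ways that matter: signatures
overlap heavily across cancer types, amplitudes are heavy-tailed,
prevalences vary per event, tumor purity dilutes amplitude, and the
cytoband universe is ~an order of magnitude larger. A ≥0.9 held-out
accuracy on a well-separated synthetic cohort therefore validates the
pipeline's mechanics (features, tuning, elimination, grouping, vote
normalization), not the clinical accuracy of SCNA-based origin
classification, which on real pan-cancer data is far lower before class
grouping. Likewise the clone-pair generator places private CTC events only
on tumor-neutral spans — by design, so the designed shared fraction is not
confounded — whereas real CTCs can overwrite tumor events.

## Numerical and degenerate-input choices

* Seeds: every generator and every stochastic stage takes an explicit seed;
  functions restore the caller's RNG state, and a full pipeline rerun from
  the same configuration is byte-identical (`summary.json` compared as
  text; wall-clock timing lives in a separate log).
* Degenerate inputs error early and explicitly: all-masked or all-zero
  count vectors, empty segment lists, empty gene lists, panels with no
  matching locus, single-class label vectors, classes smaller than the CV
  fold count, configs with a missing seed.
* The permutation p-value uses the add-one estimator $(b+1)/(B+1)$, so it
  can never be exactly zero.
* Test and acceptance problem sizes (1,200 bins, 40–100 seeds per
  experiment, 60–100 samples per class) were chosen once as the smallest
  sizes at which the checked properties are stable, and are stated in the
  relevant tests.

## Known limitations

* No allele-specific copy number, no breakpoint refinement below bin
  resolution, no BAM ingestion (counts are the input contract), no locus
  dropout model.
* Absolute ploidy is unidentifiable from ratios when odd states are scarce
  (see above).
* The 59-locus panel shipped under `inst/extdata/` is a synthetic stand-in
  whose cytoband names mirror loci recurrently altered in hepatocellular
  carcinoma; it is an editable TSV, not a citable clinical panel.
* Recurrent-SCNA discovery (GISTIC-style significance) is out of scope; the
  panel mechanism assumes a literature-derived locus list.
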