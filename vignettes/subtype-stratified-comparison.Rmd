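---
title: "Subtype-stratified comparison of in situ and invasive breast tumors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subtype-stratified comparison of in situ and invasive breast tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratomics)
```

## The problem

Ductal carcinoma in situ (DCIS) is a non-invasive breast lesion with highly
variable invasive potential; unstratified genomic comparisons of DCIS with
invasive breast cancer (IBC) tend to find few differences because both
cohorts are dominated by luminal tumors and the contrast is confounded by
intrinsic subtype. `stratomics` implements the stratified alternative:
assign each tumor an intrinsic subtype first, then compare DCIS and IBC
*within* each subtype across three genomic layers — gene expression, DNA
copy number and DNA methylation.

This vignette records the models, parameter choices and numerical
conventions behind each stage, and the reasoning behind choices the
underlying method leaves open.

## Intrinsic subtyping

Subtypes are assigned by nearest-centroid classification: each sample's
centered expression vector is Spearman-rank-correlated against a gene x
subtype centroid matrix over the genes the two share (mid-ranks for ties)
and the subtype with the highest coefficient wins; the runner-up is kept as
the "second subtype". The classifier assumes the cohort resembles its
training cohort in ER composition (about 60% ER-positive), so genes are
centered not on the plain cohort mean but on

$$m_g = w \cdot \bar{x}_{g,\mathrm{ER}+} + (1 - w)\cdot \bar{x}_{g,\mathrm{ER}-},
\qquad w = 0.6,$$

which makes the centering invariant to how many ER-positive tumors happen
to be in the cohort at hand. The weight is a parameter of
`balanced_center()` because the adjustment exists to match a training
composition, not because 0.6 is special; when `w` equals the cohort's true
ER-positive fraction, balanced centering reduces exactly to plain mean
centering (a tested invariant).

ER status itself is called from ESR1 expression, which is strongly bimodal
in breast cohorts: `call_receptor_status()` fits a two-component
equal-variance Gaussian mixture and places the cutoff at the point of equal
posterior probability between the components. A sample is positive iff its
value is *strictly above* the cutoff. We use model-based deterministic
initialisation (hierarchical agglomeration, as implemented in mclust)
rather than random EM restarts: the fit is reproducible across runs and
platforms with no seed plumbing, and for the well-separated bimodal
distributions this procedure targets the two approaches coincide. If BIC
prefers a single component, or the fitted means sit less than one common
standard deviation apart, the distribution is declared "not bimodal" and
the caller must supply a cutoff. PGR status uses the identical machinery.

*Core basal* tumors are flagged as those with correlation to the basal-like
centroid strictly greater than 0.6. The flag is computed for every sample —
restricting attention to invasive tumors is a reporting decision, so the
package computes the flag everywhere and lets reports filter.

Ties in the maximal correlation are broken toward the subtype listed
earliest in the centroid columns (with a logged message); genes present in
the centroid set but absent from the matrix are dropped, with a warning
when less than 80% of centroid genes are found. No "normal-like" class and
no minimum-correlation floor are imposed: the classifier assigns among
exactly the centroids it is given.

## Signature scores

A signature score is the mean over the signature's genes of
weight x Z-score, where Z-scores are computed per gene over the full
combined cohort (DCIS and IBC together, matching the joint normalization
context) with the sample (n-1) standard deviation — configurable, since
either convention is defensible and the choice only rescales scores by
sqrt(n/(n-1)). Adhesion-type genes enter EMT-style signatures with weight
-1, EMT genes with +1. Gene lists are configuration inputs, not hard-coded:
the canonical 11-gene proliferation and 7+4 EMT memberships live in
supplementary material of published predictors, and the scorer accepts any
signed list. External predictors with their own fitted internals
(differentiation, immune/stromal infiltration) are out of scope; their
place in the summary table can be filled by any user-supplied signed list.

## Copy number

The pipeline consumes segmented integer copy-number profiles (SEG-like
files); segmentation itself is upstream. Two summaries are derived:

* **Gene copy number** — the cn of the segment overlapping the gene's
  interval by the most base pairs; an exact tie goes to the segment with
  the smaller start (documented, tested against a brute-force per-bp
  oracle). Genes with no overlap are missing, never guessed. HER2 copy
  number is simply this lookup at the ERBB2 model — no separate code path.
* **Genomic instability index (GII)** — the fraction of the *covered*
  genome whose cn deviates from baseline. The denominator is the sum of
  segment lengths rather than a nominal genome size: uncovered regions
  carry no information. Baseline is cn = 2 by default; a per-sample
  baseline of round(ploidy) is available for cohorts with ploidy
  estimates, since instability relative to ploidy is the other reasonable
  convention and the choice is not derivable from segments alone.

Coordinates are 1-based inclusive everywhere in memory; SEG files are read
as written, BED-like files are 0-based half-open on disk and converted at
the reader boundary. This is declared once and enforced by the readers.

## Methylation

Beta values (fraction methylated, in [0, 1]) pass through a fixed QC
cascade with strict inequalities at both printed thresholds: entries with
detection p *strictly above* 0.05 become missing; CpGs with *strictly more
than* 25% missing entries are dropped; the remainder is completed by
k-nearest-neighbour imputation (k = 10, the canonical default). Neighbour
distance is the mean squared difference over jointly observed samples —
i.e. Euclidean distance rescaled by the observed fraction — with a
row-mean fallback and clipping of imputed values to [0, 1].

**Per-gene profiles.** Each gene is summarised by one number per sample:
the sample's score on the first principal component of the beta submatrix
of CpGs within the gene body ± 50 kb. PCA is computed on centered,
*unscaled* values (covariance PCA): beta values already share a scale, so
per-CpG standardisation would only up-weight noise at near-constant CpGs.
The PC sign is mathematically unidentifiable; we orient it so the profile
correlates non-negatively with the per-sample mean beta over the gene's
CpGs, making "hypermethylated" read as "higher profile" throughout.
Single-CpG genes use the centered beta directly; genes without CpGs are
absent from the output. Overlapping genes share CpGs — each gene's
neighbourhood is assembled independently, so a CpG may contribute to
several genes; this double counting mirrors the biology of overlapping
clustered genes and is deliberate.

**Differential methylation.** Within each subtype, profiles are compared
between DCIS and IBC by two-sided Mann–Whitney U tests — exact null
distribution when the combined sample size is at most 20 and untied,
tie-corrected normal approximation with continuity correction otherwise —
with Benjamini–Hochberg correction *across genes within the subtype*. A
gene is called significant only jointly: FDR q below 0.05 *and* effect
size (absolute difference of group medians of the profile) strictly above
the 80th percentile of effect sizes in that subtype. The percentile rule,
not any fixed cutoff value, is the specification: a printed companion
constant for such a filter is a property of one particular data set.
Subtypes where either group has fewer than two samples are skipped with a
notice rather than tested.

**Window score.** Long-range epigenetic silencing is scored over a
configured genomic window (by default an 800 kb window carrying 698 CpGs,
the scale on which coordinated silencing of the clustered protocadherins
has been described): each window CpG is standardised across *all* supplied
samples — tumors and normals pooled, so normals anchor the low end of the
scale — and a sample's score is its mean Z over the window CpGs. A
Spearman check against tumor purity (`window_purity_association()`) guards
against the score being an admixture artifact.

## Group statistics

Distributions of subtype and ER status between tumor types use Fisher
exact tests (the classical two-sided convention: sum of table
probabilities at most that of the observed table); 2xK tables fall back to
a seeded Monte-Carlo approximation above 200 samples. Continuous features
(purity, GII, signature scores, window mean-Z) are compared per subtype
with the same Mann–Whitney engine as differential methylation. These few
planned stratified comparisons are reported as raw p-values; multiplicity
correction is applied only in the genome-wide differential methylation
scan, where the gene dimension demands it.

## The synthetic cohort

`generate_cohort()` draws a cohort in which every downstream contrast has
a known planted truth:

* **Expression** — synthetic gene x subtype centroids with iid standard
  normal entries; a sample's centroid-gene values are its subtype's
  centroid plus N(0, `centroid_sd`) noise on the log2 scale (default sd
  0.6, roughly half the mean inter-centroid gap, giving realistic
  correlation strengths). DCIS signal is attenuated by a factor 0.7 toward
  zero, reproducing the weaker centroid correlations of in situ lesions.
  ESR1 and PGR are drawn from a two-mode Gaussian mixture (modes 4 and 10,
  sd 0.5 log2 units) with the high mode tied to receptor-positive truth;
  luminal samples are ER-positive with probability 0.9, others 0.1. An
  11-gene proliferation-like program is shifted upward by 1 log2 unit in
  basal IBC.
* **Methylation** — per-CpG baselines (window CpGs low, 0.10–0.25;
  gene-body CpGs around a per-gene level) with Gaussian noise of sd 0.08
  truncated to [0, 1]. The window shift `lres_delta` (default 0.3) is added
  to window CpGs of basal IBC samples before clipping — an additive
  beta-scale shift, the simplest model consistent with the observed
  contrast between silenced and unsilenced samples. Twenty designated genes
  receive a +0.2 shift in IBC samples of all subtypes. A Beta-distributed
  alternative generator (matched mean, precision 50) is selectable because
  the distributional form of beta values is not prescribed anywhere;
  nothing downstream depends on the choice. About 0.2% of entries are
  masked missing and 0.2% of detection p-values drawn above 0.05, matching
  the order of magnitude of real array QC losses.
* **Copy number** — per sample, recurrent subtype-specific events (5q-like
  loss in basal tumors, frequent in IBC and rare in DCIS; a focal
  17q12-like gain spanning the ERBB2 model in HER2-enriched tumors;
  16q-like loss in luminal tumors) are applied with per-event
  probabilities, then random non-overlapping aberrant intervals top the
  profile up to the cell's target aberrant fraction within ±1%; the rest
  of the genome is tiled at cn 2. DCIS targets are lower than IBC targets
  throughout, so GII contrasts have a known direction. The 5q event covers
  the methylation window, so silencing and deletion co-occur in basal IBC
  as they do in tumors.
* **Annotations** — purity is Uniform(0.3, 0.9) and recorded but does not
  mix signals (the stratified design treats purity as a covariate to
  check, not a generative component); normals carry purity 0, no subtype,
  low window methylation and baseline copy number.

The coordinate system is synthetic: six named chromosomes of equal length
(10 Mb by default). What the generator does *not* emulate: probe-level
array chemistry, realistic correlation structure of neighbouring CpGs
beyond shared per-gene baselines, subclonal (non-integer) copy number, and
purity-driven signal mixing. Tests passing on this cohort therefore
demonstrate the pipeline's correctness and calibration — they do not, and
cannot, certify performance on any particular patient cohort.

## Numerical choices and degenerate inputs

* Quantile normalization maps each sample onto the mean of per-sample
  sorted vectors; a tie group occupying sorted ranks a..b receives the
  mean of the reference values at those ranks (so the operation remains
  idempotent under ties).
* Zero-variance genes z-score to all-zero rows with a warning and are
  excluded from signature scores; zero-variance expression vectors make
  rank correlation undefined and raise an error naming the sample.
* Constant CpGs inside the scoring window contribute Z = 0 with a warning;
  an entirely constant gene neighbourhood profiles to zeros.
* Exact ties at decision boundaries always resolve by the documented
  strict inequality (receptor cutoff, core-basal threshold, detection-p
  masking, missing-fraction filter, effect-size percentile).
* Mann–Whitney switches from the exact null to the corrected normal
  approximation at combined n > 20 or in the presence of ties.

## Problem sizes

The bundled demo configuration runs 8 samples per subtype x tumor-type
cell plus 8 normals, 120 genes and 1200 CpGs — small enough that the full
pipeline completes in seconds while every stage still has planted signal
to find. The acceptance script scales this to 25 samples per cell, 200
genes and 2000 CpGs. Replicated calibration checks (FDR under the null,
window-shift detection power) use compact 80-sample cohorts with 400 CpGs
per replicate; these sizes were chosen so that calibrated rates are
estimated from at least 50–100 replicates.

## Known limitations

* The package consumes preprocessed layers (normalized expression,
  segmented copy number, normalized beta values); array preprocessing,
  segmentation and purity/ploidy estimation are upstream tools' jobs.
* Cohorts normalized together are assumed batch-compatible; no batch
  adjustment is exposed.
* The centroid set is an input. The package ships no published centroid
  values and does not re-derive them; synthetic centroids are used for
  testing and any centroid TSV of the same shape can be supplied.
* Subtype-stratified testing divides the cohort, so small subtypes (the
  luminal-B situation) are skipped rather than tested underpowered.
* With fewer than ~10 samples per group, the exact Mann–Whitney p-value
  floor (2/C(m+n, m)) limits attainable significance; the pipeline reports
  p-values as computed and leaves interpretation to the analyst.
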