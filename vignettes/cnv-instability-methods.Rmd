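---
title: "Methods: copy-number instability and PitNET prognosis"
author: "cnvprog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-number instability and PitNET prognosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cnvprog` analyzes array-CGH copy-number profiles of pituitary
neuroendocrine tumors (PitNETs) for their prognostic value: does the
amount of genome gained or deleted in a tumor predict recurrence
within five years of surgery? This vignette documents the models,
the parameter choices, and the numerical conventions, stage by stage.

## The measurement model

Each probe reports an L2R, the log2 ratio of tumor to reference DNA
fluorescence. A clonal single-copy gain shifts the expected L2R of
covered probes to `log2(3/2) ≈ +0.585`; a clonal single-copy loss to
`log2(1/2) = −1`. The synthetic generator's forward model is exactly
this dosage mean, `log2((2 + purity·Δ)/2)`, plus i.i.d. Gaussian
noise. Purity is an explicit parameter (default 1) even though the
recurrence analysis never models clonality: it lets tests probe how
calling thresholds behave when events are subclonal. The generator
deliberately omits dye bias, GC waves and batch effects; passing tests
therefore demonstrate correctness of the statistical machinery, not
robustness to those artifacts, which real arrays exhibit and which
should be handled upstream.

X and Y chromosomes are excluded throughout; the genome model is the
22 autosomes with hg19 lengths and one arm boundary each.

## Quality control: DLRS

The derivative log ratio spread is the IQR of lag-1 probe differences
divided by `1.349·√2`, computed within chromosomes only so that real
copy-number steps at chromosome boundaries never inflate it. For pure
Gaussian noise of sd σ the statistic converges to σ (differences are
N(0, 2σ²) and `IQR = 1.349·sd`). Samples with DLRS > 0.47 are
excluded (the boundary value itself is kept — the gate is a strict
inequality); LOH calling additionally requires DLRS < 0.3. Both
thresholds are conventional array-QC cutoffs and are configurable.

## Normalization and centralization

Profiles are median-centered by default (a mode-based variant is
available: which of the two an upstream normalization used is rarely
documented, and the difference only matters for heavily altered
genomes). Median-centering fails exactly when more than half the
genome sits at a non-neutral level; the centralization step repairs
this for profiles that carry at least one called alteration longer
than 5 Mb. Lacking an external anchor (the study design this package
follows anchored such profiles by FISH), we use a data-driven
surrogate: segment means are grouped into levels (1-D clustering with
a 0.1 log2 merge tolerance), and the level carrying the largest probe
mass is declared copy-neutral and shifted to 0. The offset is a pure
shift, recorded in the output, and can be overridden per sample.

This rule is not identifiable when a single altered level spans more
than half the genome: a 96%-gained genome and a 4%-deleted genome
produce the same two-level profile. The noise-free recovery tests
therefore use cohorts whose per-sample burden stays below half the
genome; on real near-whole-genome-doubled samples the offset must come
from external evidence, which is exactly why the original design used
FISH.

## Segmentation

Circular binary segmentation, per chromosome: among all circular arcs
`(i, j]` (complement and arc each holding ≥ `min_probes` = 3 probes),
find the arc maximizing the standardized mean-difference statistic
`T`, with the noise scale `s` estimated robustly as
`mad(diff(x))/√2`. Ties break toward the shorter arc, then the
leftmost. Accepted change-points split the segment and recursion
continues.

Acceptance is at significance `α = 1e-6`. Raw permutation testing
cannot reach that level (B permutations floor the p-value at
`1/(B+1)`), so the test is a documented hybrid: a coarse permutation
screen (default 39 shuffles, early-terminated as soon as the decision
is settled), and — only when the observed statistic beats every
shuffle — a Bonferroni-over-arcs Gaussian tail bound computed on the
log scale. The bound is conservative, which is what keeps the
false-positive rate on pure-noise genomes near zero, and it is the
component that makes `1e-6` operational. With the approximation
disabled the test is permutation-only and any `α` below `1/(B+1)` can
never accept — the behavior the pure-permutation reading of the
acceptance level implies.

Problem sizes used in validation: planted-breakpoint recovery runs on
10 planted plus 10 pure-noise genomes of 10^4 probes (≈ 455 per
chromosome), shift 0.585, noise sd 0.15 — recovery is ≥ 95% within ±2
probes and false change-points average below 1 per noise genome.

Segment states are gain iff mean ≥ +0.25, loss iff ≤ −0.25, both
inclusive. ±0.25 detects a single-copy event at ≈ 40% clonality; the
original analysis relied on expert review rather than a published
threshold, so the value is configurable and its sensitivity/artifact
trade-off should be kept in mind.

## Copy-neutral LOH

Vendor LOH callers are proprietary; the surrogate here is a
homozygosity-run caller on the SNP-probe channel: maximal runs of
consecutive homozygous SNP calls, restricted to copy-neutral probes
(a run inside a deletion is explained by the deletion and is not
cnLOH), reported when they reach 25 SNPs and 10 Mb. Samples failing
the DLRS < 0.3 gate return "not assessed", not an error. The
generator simulates the channel directly: baseline homozygosity 1/3,
raised to 0.98 inside cnLOH intervals and deletions.

cnLOH fractions are tracked separately from CNV burden and only
pooled into "altered" on request, mirroring the two burden analyses
(deleted+gained, and deleted+gained+cnLOH).

## Instability metrics and group comparisons

Altered fraction is the exact probe-count ratio. Whole-chromosome and
whole-arm events are declared when ≥ 90% of the unit's probes share a
direction; the threshold is exposed because no published rule exists,
and a whole-chromosome declaration suppresses its two same-direction
arm records. Two-group burden comparisons use the Wilcoxon rank-sum
test (exact when the combined n ≤ 10 and untied); more groups use
Kruskal–Wallis, with the p-value by exhaustive enumeration of group
assignments when n ≤ 10.

## Clustering

Profiles are binarized (any alteration) and compared by Jaccard
distance; two fully quiet tumors are at distance 0 by convention so a
"quiet" cluster can form. Ward clustering on a non-Euclidean Jaccard
matrix is formally improper; we adopt the squared-distance
(`ward.D2`) convention, record it in the output, and validate the
merges against an exhaustive Lance–Williams computation on small
matrices. k = 3 by default (quiet / intermediate / disrupted
structure), configurable. A three-state encoding (direction-aware
intersection) is available; binarization is the default because the
cohort structure being sought is burden-driven.

Cluster–clinical associations use Fisher's exact test (fully exact up
to 12 cells, Monte-Carlo with a fixed seed beyond) and Kruskal–Wallis
for continuous variables.

## Prognosis models

Burden enters recurrence models as `log2(altered probe count + 1)`,
so `exp(β)` is the odds ratio per doubling of altered probes. The
pseudo-count handles zero-burden tumors, which the doubling phrasing
leaves undefined; it is configurable. Models are fit by IRLS
(`stats::glm`, deviance tolerance 1e-8); significance is by
likelihood-ratio test against the model without the burden term, while
odds-ratio intervals are Wald — the standard reporting pair.
Multivariate models adjust for tumor type (whole cohort only), grade,
age and sex; within tumor types, grades 1a and 1b are merged (too few
1b tumors) and the type covariate is dropped. Covariates constant
within a scope are dropped automatically. Complete separation is
detected (fitted probabilities at machine 0/1 with diverging
coefficients) and flagged — the LRT p-value is still reported, the
Wald interval should not be trusted; no penalized fallback is applied.
Age is stored in years; the acceptance script reports its effect per
10 years.

Per-probe scans enter the probe status as a factor with reference
"normal"; probes observed in two states fit with df = 1, in three with
df = 2; constant probes are skipped and flagged, and
Benjamini–Yekutieli adjustment (valid under the strong dependence of
neighboring probes) runs over the actually tested probes only.
Per-gene scans binarize gene status (altered vs not), run univariate
and multivariate forms side by side, and adjust by Benjamini–Hochberg,
matching the coarser dependence at gene level. Gene status comes from
any-overlap interval mapping (BED input converted to 1-based
inclusive); a gene overlapped by both directions takes the larger
overlapped fraction, ties resolve to gain, and all mixed-direction
genes carry an ambiguity flag.

## Expression integration

Fold change is a linear-scale ratio of group means, sign-encoded
(−x means x-fold lower in recurrent tumors); the test is an
equal-variance Student t on log2 values, and a gene is differentially
expressed at |FC| ≥ 2 and p ≤ 0.05, both inclusive. Input intensities
are assumed linear-scale; the log2 is taken internally. The
signal-to-noise ranking `(μ₁−μ₂)/(σ₁+σ₂)` floors each group sd at
0.2·|mean| (0.2 when the mean is 0), the canonical GSEA convention
keeping the metric finite; the floor can be disabled.

Preranked GSEA uses the weighted Kolmogorov–Smirnov running sum
(weight 1), a gene-set-label permutation null (random same-size sets,
seeded — the appropriate null for a preranked list, recorded in the
output), NES by same-sign mean normalization, one-sided nominal p
within sign, and the ratio-of-tails FDR over the pooled null.
Significance is p < 0.05 and q < 0.25. Enrichment scores are verified
against a brute-force running-sum oracle and against an independent
implementation.

The integration table intersects CNV-scan-significant genes (adjusted
p < 0.05, univariate or multivariate, with separate membership flags)
with DE-flagged genes.

## The synthetic cohort

Defaults encode the study conditions the package is designed around: a
195-tumor cohort (56 gonadotroph / 11 immunonegative / 56 somatotroph
/ 39 lactotroph / 33 corticotroph), per-type probabilities of carrying
any CNV taken from the altered/non-altered counts, and per-type burden
laws calibrated so the overall median altered fraction matches the
reported per-type medians (0 / 0 / 4.8% / 38.3% / 11.1%) with the
reported maxima. Given the altered flag, burden is a scaled
Beta(1, b) draw with b solved in closed form from the required
conditional quantile. Events are drawn from a whole-chromosome /
whole-arm / focal (1–20 Mb) mix (0.4/0.3/0.3) without overlap until
the target fraction is covered; gains outnumber losses with per-type
gain probabilities (0.9 for lactotroph, where the gain excess is
strongest). Exact per-type gain:loss ratios are not published;
these values reproduce the reported medians only.

Recurrence labels come from a logistic model using only the covariates
the prognosis models adjust for: per-type intercepts solved by
`uniroot` so marginal recurrence rates match the per-type rates
(64% overall), grade effects OR 4.3 (2a) and 8.7 (2b) vs 1a/1b, age
OR 0.6 per 10 years, sex neutral, and the planted lactotroph effect
of OR 1.3 per doubling of altered probes (centered within type so the
marginal rate is preserved). No latent confounders are simulated, so
parameter-recovery tests measure estimation, not robustness to
unmeasured structure.

Validation sizes: burden calibration over 500 lactotroph draws
(median within ±5 points of target); effect recovery at n = 2000
(OR within [1.25, 1.35]); Wald CI coverage over 200 cohorts of
n = 200 (within [92%, 98%]); the end-to-end identity check runs a
noise-free 26-tumor, 4000-probe cohort through the full pipeline and
requires the recovered alteration matrix to equal the truth exactly;
the study-scale smoke run is 195 tumors × 10^4 probes.

## Numerical conventions and degenerate inputs

- Coordinates are 1-based, inclusive at both ends; BED I/O converts
  from 0-based half-open.
- Segmentation, permutation tests, Monte-Carlo Fisher and GSEA are
  deterministic given their seeds; the pipeline derives every stage
  seed from one master seed and reruns bit-identically.
- Adjusted p-values are step-up with cap at 1; BY multiplies by the
  harmonic sum c(m).
- Empty inputs degrade gracefully: an all-excluded QC partition stops
  the pipeline with empty downstream summaries, constant probes/genes
  are flagged rather than fit, and a sample with no SNP probes is
  "not assessable" for LOH.
- Infinite odds-ratio sentinels (separation) cannot be represented in
  JSON reports and serialize as null.

## Known limitations

Single-copy dosage only in the forward model (no high-level
amplifications or homozygous deletions); no subclonal mixtures beyond
a global purity; centralization unidentifiable above 50% single-level
burden; no probe-level GC/wave artifacts; the per-probe scan treats
probes independently (dependence is handled only through BY); GSEA
uses gene-set permutation, not phenotype permutation, so its null
ignores inter-gene correlation.
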