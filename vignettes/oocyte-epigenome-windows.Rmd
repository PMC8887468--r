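---
title: "Windowed multi-omic analysis of the oocyte epigenome: models, parameters and design"
author: "epiwindows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed multi-omic analysis of the oocyte epigenome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Growing mouse oocytes carry an unusual chromatin landscape: H3K4me3 is not
confined to sharp promoter peaks but spreads into broad domains over
unmethylated, CpG-rich sequence, while DNA methylation is laid down almost
exclusively over transcribed gene bodies. The two marks are mutually
exclusive, and the balance between the promoter-coupled and the
CpG-density-coupled H3K4me3 machinery shapes both the methylome and the
transcriptome of the mature oocyte. Perturbing one H3K4me3
methyltransferase redistributes the mark: losses concentrate at active,
CpG-poor promoters of genes whose expression then fails to be induced,
while gains appear over transcriptionally inactive, hypomethylated,
CpG-rich territory, frequently coinciding with regions that fail to
acquire DNA methylation (hypoDMRs), preferentially those that normally
methylate late in oocyte growth.

`epiwindows` implements the complete quantitative workflow needed to detect
and integrate these changes from sequencing data, together with a seeded
synthetic generator that emulates exactly this architecture with planted
ground truth, so that every caller can be validated for calibration (false
positive control) and power (recovery of planted effects) before being
trusted on real data.

# The three callers

## Windowed H3K4me3 differential enrichment

ChIP and input reads are counted per 5 kb running window by their
midpoints (so a non-overlapping tiling partitions the library, giving a
conservation invariant) and converted to RPKM. Windows with input RPKM
above an artifact threshold in any input sample are excluded; the
conventional threshold of 4 corresponds to roughly 10.8x flat input
coverage at mammalian genome scale (uniform coverage of a 2.7 Gb genome in
5 kb windows is ~0.37 RPKM), so on a toy genome the pipeline scales the
threshold as 10.8x the flat-coverage RPKM rather than applying 4 verbatim.

Remaining windows are transformed to `log2(RPKM + 0.1)` and aligned across
samples by a two-anchor linear normalization: for each sample the median of
windows below its 25th percentile (background anchor) and the median above
its 75th percentile (enriched anchor) are mapped onto the cross-sample
means of those anchors. This aligns both the noise floor and the enriched
range, absorbing global enrichment differences between libraries. We use
the mean of per-sample anchors (not the anchors of the mean profile) as the
reference because it makes the transform exactly idempotent. The offset of
0.1 RPKM keeps empty windows finite and compresses the noise floor; both it
and the anchor percentiles are exposed as arguments.

Differential windows are called by an empirical-Bayes moderated t-test:
per-window pooled variances `s_g^2` (df `d_g = nA + nB - 2`) are shrunk
toward a scaled inverse-chi-square prior fitted genome-wide by method of
moments on `log s_g^2` using the digamma/trigamma identities for
log-chi-square moments; the posterior variance
`(d0 s0^2 + d_g s_g^2) / (d0 + d_g)` feeds a t statistic on `d0 + d_g`
degrees of freedom. At `d0 = 0` this is the ordinary pooled t, at
`d0 = Inf` a fixed-variance Gaussian test; both limits are tested, and the
fit is cross-checked against an independent implementation of the same
moment estimator. P-values are Benjamini-Hochberg adjusted; a window is a
gain (loss) if significant with positive (negative) knockout-minus-control
difference. The test runs on per-replicate normalized values; group means
are reported as the effect size. A moderated test on two group averages
would be undefined, which is why the per-replicate route is the default.

## DMR calling over 100-CpG windows

CpG positions are grouped into consecutive non-overlapping blocks of 100
CpGs per chromosome (trailing remainders dropped), and a block is analyzed
only if every sample covers at least 10 of its CpGs. Counts are summed per
window and tested by a binomial logistic regression (methylated count out
of coverage ~ group) with a likelihood-ratio p-value on 1 df. Because a
binomial GLM with a single two-level factor has the group totals as
sufficient statistics, the replicate-level GLM deviance equals the pooled
2x2 G-statistic `2 * sum O ln(O/E)` exactly; the implementation uses that
closed form (vectorized over windows) and the test suite verifies it
against `stats::glm` per window. A window is a DMR only if additionally
the pooled-count percent difference exceeds 20 percentage points; the
percent difference is computed from pooled counts (coverage-weighted)
rather than averaged replicate percents, which weighs deep replicates
appropriately. No overdispersion term is fitted: with binomially sampled
synthetic data the raw type-I error sits in its nominal band, and this
matches the plain logistic-regression method being modeled. On real data
with biological replicate variability the raw p-values would be
anticonservative; that caveat is inherent to the method itself.

Windowing choices: both the 5 kb windows and the 100-CpG windows use
step = size (non-overlapping). Overlapping analysis windows would make
window-level multiple testing non-independent; sliding steps are supported
for display purposes only.

## Differential expression

Gene expression uses a deliberately simplified negative-binomial Wald
test: median-of-ratios size factors; per-gene moment dispersion
`max((v - mu)/mu^2, 1e-8)` from pooled within-group variances of
normalized counts, shrunk 50/50 toward a lowess mean-dispersion trend; the
log fold change of group means tested with standard error
`sqrt((1/nA)(1/muA + a) + (1/nB)(1/muB + a))`. The statistic is referred
to a Student t with `2(n - 2)` degrees of freedom rather than the normal:
the moment dispersion at n = 3 per group is noisy, and the doubled residual
df credits the variance reduction of the trend shrinkage while guarding the
tails (the normal reference was visibly anticonservative in null
simulations; the heavier-tailed reference keeps Benjamini-Hochberg calls at
zero under the null while retaining power for 2.5-fold effects at the
default depth). A gene is a DEG only if the adjusted p is below 0.05 and
|log2FC| > 1, i.e. a greater-than-2-fold fitted change. This stage is
validated by calibration and power simulation, not by output-identity with
any particular package: the scientific content here is the comparison
design and thresholds, not package internals.

# Promoter classification and integration

Promoters (TSS +/- 500 bp, isoforms merged with the 5'-most TSS) are
classified with precedence active > inactive > weak:

* active: promoter overlaps H3K27ac, or FPKM > 1;
* inactive: FPKM < 0.1, or promoter within a DNA methylated domain, or
  overlaps H3K27me3;
* weak: FPKM in [0.1, 1] (closed interval; boundary inclusivity is a
  convention of this package).

Precedence is needed because the active and inactive rules can both fire
(e.g. an expressed gene whose promoter lies in a methylated domain); all
fired rules are preserved as evidence strings. "Within a methylated
domain" means full containment of the promoter interval, not mere edge
overlap — domains are broad, and 1 bp contact is uninformative; an
`overlap` mode is available.

Cross-layer statistics are all 2x2 chi-squares without continuity
correction (so they match the hand formula `sum (O-E)^2/E`), with
Bonferroni correction over the pairwise tests actually run: two query sets
(gain, loss) by three promoter classes gives 6 tests and the familiar
0.05/6 = 0.0083 threshold. CpG-content comparisons use per-window CG
log2(observed/expected) with a two-sided Mann-Whitney U test (the
comparison is of distributions of a bounded ratio; a rank test avoids
distributional assumptions). Dinucleotide profiles add a pseudocount of
0.5 per dimer per window to keep log ratios finite in 5 kb windows, count
overlapping dimers on the forward strand only (CG is its own reverse
complement, so the headline CpG statistic is strand-invariant; the
reverse-complement symmetry of the other 15 entries is documented and
tested), and summarize window sets by the mean per-dimer log ratio.

The methylation-timing comparison pools (methylated, unmethylated) counts
of a window set at an earlier-timepoint methylome and contrasts two sets by
a 2x2 chi-square — e.g. called hypoDMRs versus a random set of
methylated-domain windows.

# The synthetic generator

The generator is the package's definition of the study conditions, not a
tuning surface. Defaults: 4 chromosomes x 5 Mb, 400 genes on a uniform
50 kb slot grid, 40 CpG islands per Mb, 3 replicates per group, 500k ChIP
reads per sample (75 bp single-end intervals in BED), Poisson(10) bisulfite
depth per CpG, 2 M RNA counts per sample, negative-binomial dispersion
0.05, planted effects of 3-fold (H3K4me3), 40 percentage points
(methylation) and 2.5-fold (expression), with 60 gains, 60 losses, 47
hypoDMRs + 3 hyperDMRs (94% hypo, the observed direction skew of this
system) and 40 down- + 40 up-regulated genes. This scale keeps the full
pipeline under a minute on one CPU while leaving thousands of null windows
(~4,000 ChIP windows, ~4,000 CpG windows) for error-rate estimation.

Structure emulated:

* background sequence with CG dimers depleted to ~40% of the i.i.d. rate
  (mimicking mammalian CpG depletion), 1 kb CpG islands at 60% of
  promoters plus intergenic islands to the configured density, and an
  unannotated CpG-rich 1 kb patch inside every gene body (the "orphan
  island" substrate on which late-methylating hypoDMRs and ectopic
  H3K4me3 gains sit);
* expected ChIP intensity per window = background + a broad-domain term
  rising with CpG count on unmethylated sequence + a promoter term rising
  with log FPKM. The monotone CpG-density relationship is a modeling
  assumption of this package (no quantitative form is established for it);
  only its direction matters for the planted contrasts;
* active genes carry H3K27ac promoters and gene-body methylated domains
  (87% methylation; 4% elsewhere), 35% of domains are flagged
  late-methylating, and an earlier-timepoint methylome leaves late domains
  unmethylated. One earlier timepoint is emitted as a separate sample
  rather than a continuous trajectory — the timing analysis needs exactly
  one;
* losses are planted at active CpG-poor promoters; half the gains at
  inactive CpG-island promoters, half on gene-body patches inside
  late-methylating domains where a hypoDMR is co-planted (the only place a
  gain may intersect a methylated domain); hyper DMRs go to unmethylated
  blocks; down-DEGs are drawn preferentially from the
  oogenesis-upregulated set and from loss-promoter genes; up-DEGs from
  genes with no H3K4me3 change;
* FPKM values are rescaled so that the genome-wide sum of FPKM x length
  (kb) equals 1e6 — the self-consistency identity of the FPKM definition —
  which makes FPKM measured from the simulated counts agree with the
  generating values, so truth promoter classes and measured classes
  coincide except at sampling noise.

Counts are negative-binomial (not Poisson) so the moderated tests face
realistic overdispersion; methylation counts are binomial at the true
per-CpG proportion, keeping the DMR test exactly calibrated in-pipeline.
Setting every effect to its neutral value (`nullSimConfig()`) yields a
null dataset with all truth labels `null`.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: read-level sequence errors and adapters,
bisulfite conversion failure, biological replicate-to-replicate
methylation variability (overdispersion beyond binomial), strand
asymmetry, repeat content, and gapped or scaffolded assemblies. Results on
real libraries depend on upstream trimming/alignment quality that this
package assumes done.

# Numerical choices and degenerate inputs

* Variance floors of 1e-8 on pooled variances and dispersions avoid
  zero-variance artifacts from duplicated values.
* `trigammaInverse` solves the moment equation by Newton iteration with
  the standard asymptotic guards; no-excess-variance data give `d0 = Inf`
  (complete shrinkage) rather than a failure.
* The G-statistic uses the `0 * log(0) = 0` convention, so complete
  separation (0% vs 100%) stays finite without iterative fitting.
* Windows with zero coverage in a group are skipped with a reason, not
  dropped silently; artifact filtering keeps windows at exactly the
  threshold (exclusion is strictly `>`).
* Ties-only inputs to the rank-sum test return p = 1.
* All randomness flows from a single integer seed through fixed per-stage
  sub-seeds; two runs with the same configuration are byte-identical (the
  manifest's timestamp aside).

# Problem sizes used in validation

The test suite exercises: the default configuration (4 x 5 Mb, above) for
recovery and directional statistics; a null default-size configuration for
calibration (>= 2,000 CpG windows for the DMR type-I band, ~4,000 ChIP
windows); 5,000-window Gaussian simulations for p-value uniformity of the
moderated test (KS distance < 0.02); 10,000 simulated variances for
hyperparameter recovery (d0 within 25%, s0^2 within 10%); and a reduced
1 x 2 Mb configuration for serialization, determinism and unit tests.
These sizes are the package's validation conditions; scaling any of them
up changes runtimes, not conclusions.

# Known limitations

* The enrichment normalization is a concrete two-anchor rendering of
  "enrichment normalisation" as practiced in interactive tools; other
  renderings (quantile or LOESS normalization) would differ in detail.
* The DMR test inherits the calibration caveat of plain logistic
  regression: no beta-binomial overdispersion.
* The DEG stage is a simplified negative-binomial test, validated by
  simulation, not a reimplementation of any specific package's shrinkage
  estimators.
* Promoter-to-window assignment uses the single valid 5 kb window
  containing the TSS; promoters whose TSS window was artifact-filtered are
  dropped from profile analyses with a count.
* The one-way ANOVA in the timecourse summary treats promoters as the
  observational unit.
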