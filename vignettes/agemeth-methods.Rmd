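---
title: "Methods: age-associated DNA methylation across tissues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: age-associated DNA methylation across tissues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agemeth)
```

# Overview

`agemeth` implements a complete analysis chain for detecting CpG sites
whose DNA methylation changes with age (ageCGs) in multiple human
tissues, combining two arms:

1. **Array arm** — two-channel methylation-array preprocessing
   (background subtraction, detection p-values, beta-scores, filtering,
   empirical-Bayes batch normalization), per-CpG linear regression of
   methylation on age, FDR control, and downstream context, overlap and
   expression statistics.
2. **Sequencing arm** — a targeted bisulfite-sequencing methylation
   caller (in-silico conversion, exact read mapping, duplicate removal,
   quality/depth-filtered pileups) and a per-target linear mixed model
   with continuous-distance AR(1) correlation that tests for a
   *widespread* age effect across neighboring CpGs.

Every stage is exercised end-to-end on synthetic data with known truth;
this vignette records the models, the parameter choices, and the design
decisions that were genuinely open.

# Array arm

## Beta-scores

Each CpG is queried by an unmethylated (A) and a methylated (B) bead
type read in a single color channel. Per sample and channel, the median
of the negative-control intensities is subtracted from every probe
intensity; the methylation estimate is then

$$\beta = \frac{B}{A + B}$$

with **no** additive correction constant in the denominator (the vendor
formula adds 100, which biases low-intensity probes). Degenerate values
are resolved by rule: $B < 0$ (methylated signal below background) maps
to 0, $\beta > 1$ (unmethylated signal below background) maps to 1, and
a non-positive total $A + B \le 0$ is treated as missing. The estimator
is invariant to a common scale on both channels, so multiplicative
chip effects cancel in $\beta$ itself.

## Detection p-values

Array software of the relevant era did not publish its detection
formula, so the package states its own, distribution-free definition:
the total signal $A + B$ is ranked against the sample's pooled
negative controls from both channels with add-one smoothing,

$$p = \frac{1 + \#\{\text{controls} \ge A+B\}}{1 + n_\text{controls}}.$$

With 200 pooled controls the smallest attainable p is $1/201 \approx
0.005$, comfortably below the 0.01 detection threshold.

## Filtering

Applied in a fixed order, because the resulting counts depend on it:
(1) entries with detection $p \ge 0.01$ are masked; (2) samples with
more than 10% missing entries are removed; (3) probes with more than
10% missing entries are removed; (4) probes flagged for a SNP (minor
allele frequency at least 3% within 15 bp of the CpG) or for ambiguous
genomic mapping are removed. Both 10% thresholds are strict
("greater than"), and the SNP boundaries are inclusive.

## Batch normalization

Beadchip batch effects are removed with the ComBat empirical-Bayes
location/scale model (via the `sva` package), one tissue at a time:
tissues were arrayed as separate experiments, so batch is confounded
with tissue and joint normalization would erase genuine between-tissue
differences. ComBat does not accept missing values; missing cells are
imputed with the per-probe mean *for the adjustment only* and restored
to missing afterwards — the simplest imputation whose effect is erased
on re-masking. The parametric prior is the package default because it
is deterministic and fast; the nonparametric variant is available as
`mode = "nonparametric"`. Output is clipped to $[0,1]$ to maintain the
beta-score invariant; probes with zero variance pass through unchanged.

## Per-CpG age regression

For each tissue separately, each probe's beta-scores are regressed on
age (years) with a binary gender covariate by ordinary least squares,
using case-wise deletion of missing values — the standard per-probe
EWAS treatment. The age effect is tested two-sided against the t
distribution. At least 4 complete observations and nonzero age variance
are required; otherwise the probe is flagged untestable. P-values are
adjusted per tissue by Benjamini–Hochberg; **ageCGs** are CpGs with
$q < 0.05$, **non-ageCGs** have $q > 0.5$, and the band between is
*intermediate* and excluded from ageCG/non-ageCG contrasts. Because
gender is coded 0/1, the reported intercept is the predicted
methylation at age 0 for the reference gender.

## Context and cross-tissue statistics

CpGs are classified against CpG island intervals (BED, 0-based
half-open): *island* inside an interval, *shore* within 2,000 bp
(boundary inclusive — "within 2 kb" is read as $\le$), *other* beyond.
Context-by-sign association is tested with Pearson's chi-squared; the
continuity-correction policy is "auto" (applied to 2×2 tables only),
which is the combination under which the published context tables
(df = 2, uncorrected) and expression tables (2×2, corrected) are both
reproduced to their printed precision.

Slope magnitudes are compared across context × tissue × sign with a
three-way fixed-effects ANOVA after a Box–Cox power transform; λ is
chosen by maximizing the profile log-likelihood of an intercept-only
model over the grid $[-2, 2]$ in steps of 0.01 (λ = 0 is the log).
The ANOVA uses sequential (type-I) sums of squares in the factor order
context, tissue, sign; the order is a documented choice since the
original analysis does not state one, and it is configurable by
permuting the input factors.

Cross-tissue overlap of ageCG sets is tested by permutation: each
replicate draws per-tissue random sets of the observed sizes from the
probe universe and records the all-tissue intersection; the empirical
p-value uses add-one smoothing, so $p < 10^{-4}$ is representable only
with at least 10,000 replicates (the default). Gene-level
unique/shared classes use the representative CpG with the smallest age
p-value per gene (ties broken by probe id, deterministically): a gene
is unique to a tissue when $q < 0.05$ there and $q > 0.5$ in all
others, shared when $q < 0.05$ everywhere; a gene with any
intermediate q among the "other" tissues is neither.

Expression linkage uses FPKM thresholds: expressed $> 0.25$,
non-expressed $< 0.05$; genes between the thresholds are excluded from
enrichment tables, which matters for marginal totals and is therefore
stated here. Enrichment is tested by chi-squared (auto correction) by
default; a Fisher exact option exists because recomputing the published
unique/shared table reproduces its kidney and muscle p-values exactly
under the exact test but not under chi-squared, while the brain cell is
not reproduced under either and remains unattributed. Rank-sum
comparisons of expression exclude zero-FPKM entries.

## Chromatin landscape summaries

Distance to CTCF binding sites is measured from the CpG to the nearest
peak *midpoint* (`floor((start+end)/2)` in 0-based space — the floor
shifts all distances equally and cancels in the >5 kb dichotomy);
chromosomes without peaks fold into the >5 kb class. LAD membership
uses interval containment; the edge distance is normalized by domain
length (range $[0, 0.5]$). Orientation is defined here explicitly, as
the original description is terse: a CpG's gene points *toward* the
nearest LAD edge iff moving in the transcription direction decreases
the distance to that edge. Chromatin-state enrichment is the ratio of
the positions' state share to the state's share of the tiled genome;
the segmentation must tile its chromosomes exactly once, and is
consumed as input intervals (no state learning).

# Sequencing arm

## Caller

The reference and the forward-mate reads are bisulfite converted in
silico (C→T on the plus strand; reverse mates are reverse-complemented
first), and converted reads are mapped to converted targets by exact
unique substring match, forward orientation only — capture selects the
original top strand. This replaces a general-purpose short-read aligner
deliberately: targets are short promoter regions, the scientific
content is the conversion/pileup logic, and an exact-match policy makes
every mapping decision auditable. A read matching at two or more
offsets anywhere is ambiguous and discarded. Duplicates — reads with
identical (sample, target, offset, mate) — keep the highest
mean-quality copy (ties by read id); the duplicate definition is
coordinate-based since the original is unstated.

Pileups use the original unconverted sequences re-attached after
mapping: at each reference CpG cytosine, an original C with phred
$\ge 30$ counts methylated and a T unmethylated; other bases and
low-quality bases are ignored. Percentages are reported only at depth
$\ge 20$. Young-minus-old deltas are differences of group medians per
CpG. Method agreement with the array is summarized per sample by
Pearson correlation over shared CpGs (array $\beta \times 100$) and by
Bland–Altman limits of agreement, $\bar d \pm 1.96\,\mathrm{sd}(d)$.

Only plus-strand CpG calls are made. Mates are processed independently
after conversion; overlapping mates would double-count except where the
duplicate rule removes them — a documented limitation of the
insert-unaware design.

## Regional mixed model

Per target, percent methylation is modeled as

$$\mathrm{pct}_{ij} = \beta_0 + \beta_{\mathrm{age}}\,\mathrm{age}_i +
\beta_{\mathrm{pos}}\,\mathrm{pos}_j + b_i + \varepsilon_{ij},\qquad
b_i \sim N(0, \sigma^2_b),$$

with within-sample residual correlation
$\mathrm{Corr}(\varepsilon_{ij}, \varepsilon_{ij'}) =
\phi^{|\mathrm{pos}_j - \mathrm{pos}_{j'}|}$ — continuous-distance
AR(1) (`corCAR1`), which handles the irregular CpG spacing natively.
Estimation is REML through `nlme` (the software family the model
originates from), with ML available for likelihood-ratio comparisons.
Position enters the fixed effects centered and in kb to avoid
ill-conditioning; correlation distances stay in bp, so φ is reported as
the correlation at 1 bp separation. Rows with missing percentages
(depth below threshold) are dropped.

Two structural choices were open and are both implemented: the random
structure defaults to a per-sample random intercept plus AR(1)
residuals; `random_intercept = FALSE` pins $\sigma^2_b = 0$ and fits
generalized least squares with the same correlation, and `ar1 = FALSE`
pins $\phi = 0$, under which (with both pinned) the fit reduces
*exactly* to ordinary least squares — the reduction is verified against
an independent normal-equations oracle in the tests.

Fixed effects are tested by Wald statistics. The default reference is
the t distribution with $n_\mathrm{samples} - 2$ degrees of freedom:
age varies between samples, so between-sample information drives the
test, and simulation at the validation-cohort size (19 samples,
30 CpGs) shows the normal reference rejects a true null in roughly 10%
of targets at nominal 5% whereas the t reference stays within the 8%
bound the package tests itself against; `df_method = "normal"` remains
available. The interaction variant adds an age × position term
(position centered before multiplication) to detect age slopes that
change along the target; it is inestimable with a single CpG. Across
targets, Benjamini–Hochberg is applied to converged fits and a target
is flagged as carrying a widespread age effect at $q < 0.05$. Merging
data from two capture targets into one model is refused unless they
share samples (an explicit `merge_targets` flag covers the legitimate
overlapping-target case).

# Synthetic data

The generator produces every input the pipeline consumes, with truth
tables, so all parameter-recovery claims in the tests are checkable.
All randomness derives from the config seed; identical configs give
identical outputs.

**Annotation** — one synthetic chromosome (`chrS`, 10 Mb by default)
carries disjoint CpG islands, stranded genes (half anchored with their
start at an island, linking islands to genes), CTCF peaks, disjoint
LADs, and a chromatin-state segmentation that tiles the chromosome
exactly. One chromosome keeps interval logic trivial; multi-chromosome
support is not needed for testing.

**Array study** — the default conditions are 4 tissues × 40 samples,
ages uniform on 20–90 y, 2,000 probes with 5% carrying a true age
effect. Following the dichotomy the analyses assume, half of the true
probes sit in islands with small shared positive slopes
(0.001–0.002 β/year, hypomethylated baselines) and half sit outside
islands with larger tissue-specific negative slopes (0.002–0.004
β/year, hypermethylated baselines). True probes are placed in gene
clusters of 2–4 with slopes drifting as a random walk in position
(step sd `5e-4` per √kb), so neighboring CpGs agree in sign and differ
less when close — the property the neighbor-concordance statistics
measure. A 0.02 additive β offset on a random 5% of probes for one
gender exercises the covariate. Intensities follow
$B = \beta T + \mathrm{bg}$, $A = (1-\beta) T + \mathrm{bg}$ with a
lognormal per-probe scale $T$ (mean 4,000, CV 0.3) and background
(mean 200, sd 30) whose *level* varies per sample (lognormal CV 0.2)
and is shared with the negative controls — the simplest model whose
beta estimator is unbiased after control-based subtraction, and which
gives subtraction something real to remove. Batch effects act on the
beta scale (default +0.05 on the second chip), additively per channel
on intensities, and multiplicatively on everything including controls.
β noise is Gaussian (sd 0.03); 1% of cells drop to background only,
feeding the detection filter; 1% SNP and 1% multi-mapping flags feed
the annotation filter.

**Expression** — gene FPKM is lognormal; genes hosting tissue-specific
negative effects are boosted 8× in their target tissue, and 30% of
genes are silent (FPKM < 0.05) everywhere.

**Bisulfite reads** — the truth surface combines a smooth positional
baseline (midpoint 50%, amplitude 20%), a linear age effect (0.5
percentage points/year, centered at age 60), and per-sample deviations
with AR(1) spatial correlation (per-bp φ 0.993, i.e. ≈0.5 at 100 bp;
sd 5%). Reads (72 bp, matching the platform's read length; single-end
by default since mates are processed independently downstream) are
drawn at uniform starts at ≈50× per-CpG depth for a 9-young/10-old
cohort; CpG cytosines retain C with probability m/100, non-CpG
cytosines convert except for a 0.5% failure rate, sequencing errors
arrive at 0.1% per base, and 5% of base qualities fall below phred 30.
`simulate_regional_pct()` generates the mixed model's input directly
(bypassing reads) for calibration studies.

**What the generator does not emulate** — bead-level Illumina noise,
dye bias, probe cross-hybridization chemistry, paired-end insert
geometry, capture-efficiency variation, cell-composition heterogeneity,
and genuine genomic CpG density patterns. Passing tests therefore
demonstrate algorithmic correctness and statistical calibration under
the stated generative model, not robustness to every artifact of real
arrays or libraries.

# Problem sizes and runtime choices

The shipped checks use sizes chosen to make the statistical claims
meaningful while keeping the suite quick to run routinely: truth
recovery on the default 4 × 40 × 2,000 configuration averaged over
5 seeds; null calibration with 100 age permutations of a 500-probe
tissue; 10,000 overlap permutations; 200 null and 100 effect
replicates of the 19-sample × 30-CpG regional design; Box–Cox recovery
at n = 2,000. The acceptance script
(`scripts/acceptance.R`) recomputes the same quantities from scratch
under a caller-supplied seed.

# Known limitations

- The detection p-value is a stated stand-in for an unpublished vendor
  formula; absolute detection rates are not comparable to vendor
  output, though the 0.01 threshold semantics are.
- The exact-match mapper is not a general aligner: reads with
  sequencing errors in the mapped portion are dropped rather than
  aligned with mismatches (a `max_mismatch`-style relaxation is out of
  scope; at the simulated 0.1% error rate ≈7% of 72-mers are lost,
  uniformly over positions).
- Clipping beta-scores at 0/1 and methylation at 0/100 introduces
  point masses that mildly attenuate slopes for probes near the
  boundaries.
- The Wald t reference with $n-2$ df is an approximation; it is
  validated by simulation at the shipped design sizes, not derived.
- Only plus-strand CpG methylation is called; CHH/CHG contexts and
  reverse-strand calls are out of scope.
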