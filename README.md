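# agemeth

Multi-tissue analysis of age-associated DNA methylation in R.

DNA methylation at CpG dinucleotides drifts with age, and the drift is
structured: CpGs inside CpG islands tend to gain methylation with age in
a pattern shared across tissues, while CpGs outside islands tend to lose
methylation in tissue-specific ways. `agemeth` is for epigenomics
researchers who want a tested, reusable implementation of the full
analysis chain that detects and characterizes these **age-associated
CpGs (ageCGs)** — from raw two-channel methylation-array intensities and
targeted bisulfite-sequencing reads through to the statistics describing
CpG-island context, cross-tissue sharing, gene-expression linkage, and
chromatin landscape.

## What it computes

**Array arm.** Per sample and color channel, the median negative-control
intensity is subtracted and methylation is estimated as the beta-score

&beta; = B / (A + B)

(methylated over total signal, with *no* vendor +100 correction;
negative B clips to 0, negative A clips to 1). After detection-p and
missingness filtering and ComBat empirical-Bayes batch normalization
(per tissue), each CpG is regressed on age with a gender covariate:

&beta;<sub>ij</sub> = b<sub>0</sub> + b<sub>age</sub>·age<sub>j</sub> + b<sub>sex</sub>·sex<sub>j</sub> + e<sub>ij</sub>

P-values are Benjamini–Hochberg adjusted per tissue; **ageCG**: q < 0.05,
**non-ageCG**: q > 0.5. Downstream: island/shore/other context calls and
chi-squared context×sign tests, Box–Cox-transformed ANOVA of slope
magnitudes, multi-set overlap permutation tests, gene-level
unique/shared calls, FPKM expression enrichment, CTCF-distance, LAD and
chromatin-state summaries.

**Sequencing arm.** Reads and reference are bisulfite-converted in
silico, mapped by exact unique substring match (forward strand only),
deduplicated, and piled up: percent methylation per CpG from phred ≥ 30
bases at depth ≥ 20. Per target, a linear mixed model

pct<sub>ij</sub> = &beta;<sub>0</sub> + &beta;<sub>age</sub>·age<sub>i</sub> + &beta;<sub>pos</sub>·pos<sub>j</sub> + b<sub>i</sub> + &epsilon;<sub>ij</sub>,  Corr(&epsilon;<sub>ij</sub>, &epsilon;<sub>ij'</sub>) = &phi;<sup>|pos<sub>j</sub> − pos<sub>j'</sub>|</sup>

(random intercept per sample, continuous-distance AR(1) residuals,
REML) tests for a *widespread* age effect across neighboring CpGs, with
an age×position interaction variant and per-target FDR.

A synthetic-data generator (`sim_config()`, `simulate_annotation()`,
`simulate_array_study()`, `simulate_fpkm()`, `simulate_bisseq()`)
produces every input with known truth, so the whole chain is testable
without external data.

## Worked example

Simulate the default study (4 tissues × 40 samples, 2,000 probes, 5%
true age effects) and run the array arm:

```r
library(agemeth)

cfg   <- sim_config(seed = 42)
ann   <- simulate_annotation(cfg)
study <- simulate_array_study(cfg, ann)
res   <- run_array_pipeline(study$panel, study$sample_sheet, study$probes)

res$manifest$n_agecg
#>  blood  brain kidney muscle
#>     49     60     54     50

head(subset(res$combined, tissue == "kidney" & class == "ageCG",
            select = c(probe_id, slope, intercept, p, q, r2)), 5)
#>      probe_id       slope intercept            p            q        r2
#> 3985  cg00064 0.001040438 0.1560017 5.387059e-05 2.456749e-03 0.3916408
#> 3988  cg00067 0.001391692 0.2158460 5.869686e-06 3.488016e-04 0.4406238
#> 4082  cg00162 0.001786216 0.2213208 2.558836e-10 4.561706e-08 0.6667996
#> 4089  cg00170 0.001984243 0.1527042 8.450048e-10 1.274657e-07 0.6473926
#> 4090  cg00171 0.002648151 0.2411139 4.352206e-04 1.673466e-02 0.3013114
```

Each row is one CpG in one tissue: `slope` is the methylation change
per year of age (Δβ/year — e.g. cg00170 gains ≈0.14 β over 70 years),
`intercept` the predicted methylation at age 0, `q` the BH-adjusted
p-value that makes it an ageCG, and `r2` the model fit. Context
summaries reproduce the expected sign structure — most ageCGs are
positive (island gains shared across tissues):

```r
ctx <- classify_context(study$probes$cpg_pos, ann$islands)
ctx$probe_id <- study$probes$probe_id
context_sign_summary(res$combined, ctx)$by_tissue
#>   tissue n_agecg pct_positive pct_negative
#> 1  blood      49     77.55102     22.44898
#> 2  brain      60     75.00000     25.00000
#> 3 kidney      54     74.07407     25.92593
#> 4 muscle      50     80.00000     20.00000
```

The sequencing arm runs the same way from reads:

```r
bis <- simulate_bisseq(cfg)
seq_res <- run_bisseq_pipeline(bis$reads, bis$targets, bis$truth$ages)
seq_res$fits[, c("target_id", "beta_age", "p_age", "phi", "converged")]
```

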