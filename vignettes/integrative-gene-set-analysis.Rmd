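---
title: "Gene set based integration of DNA methylation and gene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene set based integration of DNA methylation and gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the method answers

An exposure such as daily smoking leaves a reproducible footprint on blood
DNA methylation: dozens to hundreds of CpG sites shift by a few percentage
points of methylation. Whether those shifts have transcriptomic
consequences is harder to establish, because the induced expression changes
of any single nearby gene are usually too small for a gene-wise
differential-expression test to detect. methroast implements a system-level
alternative: pool the genes whose genomic regions carry exposure-associated
CpGs into *direction-by-region gene sets* (for example, "genes with
hypomethylated CpGs in their gene body") and ask, with a self-contained
gene set test on the expression data from the same individuals, whether the
set as a whole responds. Small but coordinated shifts that are invisible
gene by gene become detectable at the set level.

The pipeline has three statistical cores, all implemented in this package:

1. **Per-feature moderated association scans.** Each CpG's beta value (or
   each gene's log2 expression) is regressed on the binary exposure with
   covariate adjustment. With `G` features and residual variances `s_g^2`
   on `d` degrees of freedom, an empirical-Bayes prior
   `sigma_g^2 ~ s0^2 d0 / chisq_{d0}` is fitted by the method of moments on
   `log s_g^2`, and inference uses the posterior variance
   `s~_g^2 = (d0 s0^2 + d s_g^2) / (d0 + d)` with `d0 + d` degrees of
   freedom. This stabilises the denominator of the t-statistic when `d` is
   small and reproduces the ordinary t exactly as `d0 -> 0`.

2. **Gene-set construction.** CpGs passing the family-wise threshold
   `alpha / n_tests` (strict inequality; with `alpha = 0.05` and 769,683
   autosomal probes this is 6.5e-8) are split by coefficient sign into
   hypo- and hypermethylated, and mapped through the probe annotation to
   genes per region label (TSS1500, TSS200, 5'UTR, 1stExon, Body, 3'UTR,
   ExonBnd). The derived `Promoter` category is the union of TSS200,
   TSS1500, 5'UTR and 1stExon. This yields 16 sets (8 categories x 2
   directions), kept even when empty. Genes that are *themselves*
   differentially expressed (BH FDR below the configured cutoff, plus any
   user-supplied list) are removed, so a positive set-level result cannot
   be driven by genes a univariate analysis would already have found.

3. **Rotation gene set testing.** For each set, every member gene's data
   vector is reduced to the (d+1)-dimensional subspace spanned by the
   exposure effect (orthogonalised against the other covariates) and the
   residual space, via one QR factorisation of the design. Under the null
   the reduced vector is spherically symmetric, so replacing the effect
   axis by a uniformly random unit direction — the *same* direction for
   every gene within a rotation, which is what preserves inter-gene
   correlation and distinguishes rotation from gene permutation —
   regenerates null draws of the set statistics. With `b` of `nrot`
   rotations reaching the observed statistic, `p = (b + 1) / (nrot + 1)`,
   so the smallest attainable p-value is `1 / (nrot + 1)`. Three
   alternatives are reported per set: `up` (mean moderated t), `down`
   (its negative) and `mixed` (mean |t|; mean t^2 with
   `set_statistic = "msq"`), and BH adjustment runs across sets separately
   within each hypothesis column.

## A worked run on synthetic data

```{r, eval = FALSE}
library(methroast)

cfg <- pipeline_config(
  simulate = sim_config(
    n_samples = 200, exposure_fraction = 0.25,
    n_genes = 300, probes_per_gene = 8,
    n_affected_per_region = c(Body_hypo = 12),
    delta_beta = 0.1, delta_expr = 0.5,
    noise_sd_meth = 0.3, noise_sd_expr = 0.5, seed = 3),
  ewas_n_pcs = 5, dge_n_pcs = 5,
  roast = roast_config(nrot = 999),
  seed = 11)
res <- run_pipeline(cfg)
res$roast[, c("set", "n_genes", "p.up", "FDR.up", "p.mixed", "FDR.mixed")]
autoplot(res$roast)
plot_qq(res$ewas)
```

The planted hypomethylated-Body set attains the smallest `p.up` of the 16
sets; the remaining non-empty sets are small spill-over sets fed by
multi-gene probes.

## What the synthetic cohort emulates — and what it does not

The generator is first-class, tested code with a truth ledger, not a
fixture. Its defaults describe the cohort structure the method was designed
for: 1114 participants with 150 exposed (a 13.5% exposure fraction), age
34–49, both sexes, BMI, alcohol consumption and a three-level socioeconomic
indicator as covariates whose distributions differ between exposed and
unexposed (alcohol and socioeconomic status substantially so), inducing
genuine confounding. Methylation is simulated on the logit scale —
bimodal baselines typical of array data, per-probe covariate coefficients,
optional Dirichlet-mixed cell-composition structure, Gaussian noise — and
inverse-logit transformed, which keeps beta in (0, 1) without truncation
artifacts. Exposure effects are planted as the logit shift that moves each
affected probe's baseline by the requested beta-scale difference, so the
ledger's `delta_beta` is on the reported scale. On the expression side,
genes linked to hypomethylated probes are shifted up by `delta_expr` and
genes linked to hypermethylated probes down, encoding the expected
direction of methylation–expression coupling.

Default effect and noise magnitudes, chosen once: `delta_beta = 0.02` sits
inside the 0.006–0.034 range of genome-wide-significant smoking
coefficients on the beta scale; `delta_expr = 0.1` log2 units is a
deliberately small coordinated shift (the regime the set-level test
exists for); logit-scale noise SD 0.3 gives beta-scale SDs of roughly
0.02–0.07 depending on the baseline, matching blood methylation arrays;
log2 expression noise SD 0.3 is typical of array residuals. Annotation
structure: 20% of probes are intergenic and 5% of gene-linked probes link
to two genes, mirroring real array annotation; each gene gets at least one
probe per region label so region cells are always plantable.

What the generator does **not** emulate: probe-level measurement artifacts
(detection failures are all-pass in simulated data, so the QC detection
rule is exercised by dedicated tests instead), spatial correlation of
neighbouring CpGs, heavy-tailed expression noise, and any genuine causal
link from methylation to expression — the coordinated shifts are planted
jointly, so passing tests demonstrate recovery of coordinated signal, not
causal inference.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.05 | family-wise level; DMP threshold is `alpha / n_probes`, strict `<` |
| `dge_fdr_cutoff` | 0.05 | BH FDR defining DEGs removed from the sets |
| `ewas_n_pcs` / `dge_n_pcs` | 30 / 10 | response-matrix PCs added to the designs to absorb structure and batch; automatically capped so the residual degrees of freedom stay positive |
| `nrot` | 9999 | rotations; p-value floor `1/(nrot+1)` |
| `set_statistic` | `"mean"` | set summary; `"msq"` changes only the mixed statistic |
| `detection_p_threshold` | 0.01 | per-measurement detection cutoff |
| `probe_fail_sample_fraction` | 0.01 | a probe is dropped when it fails detection in more than this fraction of samples |

Two QC conventions deserve a note. The sample-level rule defaults to the
*mean* detection p-value being below the threshold; a literal *sum* across
hundreds of thousands of probes is kept available as a config option but
is not a sensible default. Likewise the probe-level failure fraction is a
parameter with the field's conventional ~1% default; pipelines occasionally
state much larger fractions and the parameter accommodates them without
guessing intent.

## Numerical and design choices

* **Beta values are modelled directly** in the EWAS (not M-values), so
  coefficients are interpretable as methylation-proportion differences;
  the heteroscedasticity this implies is part of what variance moderation
  absorbs.
* **Prior estimation** inverts the trigamma function by Newton iteration
  to tolerance 1e-8; when the log-variances show no excess dispersion over
  `trigamma(d/2)` the estimator returns `d0 = Inf` and pools completely —
  reported, not an error. Features with zero residual variance are flagged
  and excluded from prior estimation.
* **The variance prior is estimated once from all genes** and held fixed
  across rotations and sets; re-estimating per rotation would let the
  prior absorb part of the effect being tested.
* **One-sided up/down and the mixed p-value are computed from the same
  rotation draws**; no extra rotations are spent, and `p.mixed` is not
  constrained relative to the directional p-values.
* **PCA sign convention**: each component's largest-magnitude loading is
  made positive, so scores are fully deterministic across platforms.
* **Deconvolution** solves non-negative least squares per sample
  (Lawson–Hanson) and renormalises to the simplex when `sum_to_one = TRUE`
  (the default); in the design matrix the largest estimated compartment
  (granulocytes, typically) is dropped to avoid collinearity with the
  intercept.
* **The inflation factor lambda is a diagnostic only**: it is computed and
  logged but never used to rescale p-values.
* **Physical-activity-style covariates** that are strongly collinear with
  the exposure are representable but deliberately absent from the default
  covariate set.
* **Ties and determinism**: every stochastic step (simulation, rotations)
  runs under an explicit seed, with per-set sub-seeds derived
  deterministically from the master seed; identical configs give
  byte-identical artifacts. A gene may appear in both hypo and hyper sets
  of the same region if distinct probes support both directions; this is
  allowed and visible in the provenance column.

## Problem sizes used by the shipped checks

The test suite and the acceptance script exercise the pipeline at sizes
chosen for tight feedback loops while keeping every estimate stable:
rotation-test calibration uses 500 null replicates of a 10-gene set among
60 genes at n = 16 with 199 rotations (independent and exchangeable
inter-gene correlation 0.3); prior recovery uses 20,000 features at n = 8;
the end-to-end recovery run uses 200 samples, about 3,000 probes, 300
genes and 999 rotations. The full-scale defaults (1114 samples, 30/10 PCs,
9999 rotations) remain the package defaults.

## Known limitations

Set construction maps probes to genes only through the supplied annotation
(cis, symbol-string identity, no alias resolution, no enhancer or
CpG-island context). The rotation test is self-contained: it asks whether
a set responds at all, not whether it responds more than a random set of
comparable size (no competitive test is provided). Raw-intensity
preprocessing — background correction, dye-bias and quantile
normalisation, detection p-value computation, sex prediction — is upstream
of this package's contract, which starts at matrices plus annotation.
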