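---
title: "Integrative miRNA-gene network analysis: models, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative miRNA-gene network analysis: models, calibration, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mircircuitnet)
```

## The analysis in one paragraph

mircircuitnet analyses matched microRNA and gene expression profiles across
three tissue classes — normal colon mucosa (N), primary tumor (T), and liver
metastasis (M) — to identify miRNAs whose expression changes during tumor
progression, the target genes those miRNAs plausibly repress, the regulatory
networks and miRNA–transcription-factor circuits they form, the pathways they
perturb, and their association with patient survival. Because miRNAs acting on
mRNA stability leave a footprint of *negative correlation* between their own
expression and that of their true targets, sequence-based target predictions
can be filtered down to expression-supported relations; everything downstream
builds on that filtered relation set.

## Pipeline stages and their models

### Feature filtering

Three filters precede inference, mirroring standard array practice:

* **Detection** (`filter_mirnas_by_detection`): a miRNA must be detected in at
  least 20 samples, *except* when all of its undetected samples fall in a
  single tissue class. The exemption is deliberate: a miRNA silent only in
  metastases is a biological signal, not background. When no detection-call
  matrix is given, detection defaults to log2 signal above 1.0 (near array
  background); both knobs are exposed. The one-class rule is implemented as an
  exemption (keep the feature) rather than per-class counting — the weaker,
  more inclusive reading — and is flagged here as an interpretation.
* **Variability** (`filter_genes_by_variability`): genes are ranked by
  variance of their log2 profile and the least variable 30% are dropped;
  retained count is `floor((1 - f) * n)`, which maps 22,517 genes to exactly
  15,761 at `f = 0.30`. Variance on the log2 scale (not CV or IQR) is the
  conventional reading of "profile variability"; ties break by input order so
  the filter is deterministic.
* **Mean signal** (`filter_by_mean_signal`): miRNAs with mean log2 signal at
  or below 5 — the conventional mid-scale cut on a 0–15 log2 scale, roughly
  the average miRNA signal — are excluded before correlation testing, because
  weakly expressed miRNAs yield correlations dominated by noise. The default
  scope is the mean over all samples; a per-class scope (keep a feature whose
  mean clears the floor in at least one class) is available for analyses that
  must retain miRNAs silenced in one class.

### SAM differential expression

Differential miRNAs and genes are found with Significance Analysis of
Microarrays in its canonical form: the relative difference
`d = (mean_A - mean_B) / (s + s0)` with `s` the pooled standard error and `s0`
the fudge factor chosen, over the {0, 5, ..., 100} percentiles of the
per-feature `s` distribution, to minimize the coefficient of variation of the
within-window spread of `d` (windows are `s`-quantile groups; ties take the
smallest percentile). Observed order statistics of `d` are compared with their
expectation under label permutations; for each threshold delta, asymmetric
cutoffs are found by scanning outward from the origin of the
quantile–quantile curve, and the FDR estimate is
`pi0 * median permuted call count / observed call count`, with `pi0`
estimated from the fraction of observed `d` inside the central 50% of the
permuted distribution. Delta is tuned to the smallest grid value whose
estimated FDR is at or below the target (default 0.01). The FDR-versus-delta
curve is monotonized (running minimum), and a feature's q-value is the
smallest estimated FDR over thresholds at which it is called — the usual
convention, which keeps `called => q <= target` true by construction.

Unpaired permutations draw distinct label assignments without replacement up
to `n_permutations` (default 1000; reported runs use at least 100); the
paired design reduces to one-sample SAM on within-patient differences with
sign-flip permutations, dropping incomplete pairs with a warning. That
reduction is the standard construction and is flagged as an assumption.

Differential-miRNA *selection* for network induction applies two further
screens, kept separate from the SAM call so they compose: `|log2FC| > 3`
(read on the log2 scale, i.e. 8-fold linear — consistent with log2 usage
throughout; a flag allows the linear-ratio reading, 3-fold) and mean
expression above background (default 5) in at least one contrasted group.

### Expression-supported targets

Every predicted (miRNA, gene) pair whose members survive filtering is tested
with Pearson correlation across the samples assayed on both platforms —
across all tissue classes jointly, since a single network is built over
N+T+M. The p-value comes from the `t = r sqrt(n-2)/sqrt(1-r^2)` transform;
Benjamini–Hochberg correction runs over all *performed* tests (the set of
tested pairs is reported, since the correction universe affects q-values).
Supported relations require `q <= 0.01` and `r < 0`. BH is the default
because it is deterministic and conservative; a Storey-style q-value with
`pi0` estimation sits behind a flag, since "q-value" is ambiguous between
the two. Multiple predictions for one pair (different target sites) collapse
to a single test to avoid double-counting in the correction. The realized
correlation cut — the least negative supported `r` — is reported for
transparency; it is a consequence of the FDR threshold and the data, not a
constant of the method.

### Networks and circuits

The induced post-transcriptional network has exactly the selected
differential miRNAs and their supported targets as nodes; target genes that
are themselves differential are flagged, and up- and down-regulated
components are reported separately. The mixed miRNA–TF network adds
candidate transcriptional edges from a validated TF-interaction table,
scored by expression correlation over the same matched samples: TF edges
accept either correlation sign (activation or repression), miRNA edges
remain negative-only, and BH runs within each edge class. Genes are first
restricted to the top 75% by expression difference, operationalized as the
maximum absolute class-mean log2 difference over the T-vs-N and M-vs-T
contrasts (an interpretation, since "greatest differences in expression"
admits several readings).

Two triangular feed-forward circuit types are enumerated exhaustively over
retained edges: TF-driven (TF→miRNA, TF→gene, miRNA⊣gene) and miRNA-driven
(miRNA⊣TF, miRNA⊣gene, TF→gene). Each circuit's three edge p-values are
combined by Fisher's method (chi-squared with 6 df); no combination rule is
canonical for this step, so the combined p is reported alongside the
individual edges and a per-edge-significance-only reading is available by
ignoring it. Feedback pairs (miRNA⊣TF together with TF→miRNA) are visible in
the edge table but are not enumerated as circuits.

### Pathway perturbation

Gene sets are tested with a two-directional set-level z statistic on
per-gene Welch t contrasts: `z = (mean_set - mean_all) * sqrt(|S|) / sd_all`,
with one-sided normal tails for up/down and a two-sided tail for the
default both-directions test. This is the parametric core of the
generally-applicable set-enrichment approach; the full method's one-on-one
sample pairing with meta-combination is deliberately not reproduced — the
group-statistic form is simpler, calibrates correctly at these set sizes
(type-I error 0.05 ± 0.02 in the suite), and the finite-population
correction omitted by the z form only makes the test slightly conservative.
Two universes implement the two enrichment strategies: all supported targets
of differential miRNAs (strategy A), or only those targets that are
themselves differentially expressed (strategy B, more conservative). Raw
p-values at 0.05 flag significance; whether to adjust across pathways is
left to the caller (a BH pass over the output is one line).

### Survival screening

Each panel miRNA enters a univariate Cox proportional-hazards fit — only
univariate, deliberately, given cohort sizes in the tens — with Breslow tie
handling by default (Efron behind a flag; the choice is not dictated by the
data sizes involved). Fits are delegated to the `survival` package; results
report the hazard ratio per unit (log2) covariate with its 95% Wald
interval, and monotone-likelihood degeneracy is surfaced as
`converged = FALSE` rather than a spurious estimate. Bonferroni control over
the panel is reported both ways — per-test alpha (`0.05/26 ≈ 0.002` for the
reference panel size) and adjusted p-values (`min(1, m p)`) — since either
convention may be wanted downstream. Kaplan–Meier curves use the
product-limit estimator after median dichotomization, with ties at the
median assigned to the low group; the median survival is the first time the
curve reaches 0.5 or below, undefined if never reached.

## The synthetic cohort: what it emulates, and what it does not

`generate_cohort()` reproduces the statistical structure the analysis
assumes, with every planted effect recorded for recovery measurement:

* **Design**: 46 patients; 78 miRNA-assay samples (23 N / 31 T / 24 M) and
  80 gene-assay samples (23 N / 30 T / 27 M) with 77 samples on both
  platforms, built from triplet, pair, and singleton patients. (The
  reference cohort's published per-assay M counts and matched-M count are
  mutually inconsistent by one sample; the design here keeps the per-assay
  class counts and realizes the 77 matched total as 23 N + 30 T + 24 M.)
* **Signal**: per-feature baselines uniform on [3, 9] log2 units with unit
  Gaussian sample noise, clipped to [0, 15] (clip events are counted).
  Baselines below the signal floor of 5 are common by construction,
  reflecting that most miRNAs are weakly expressed; planted-effect features
  draw baselines from [5.5, 9] because the analysis explicitly restricts
  itself to well-expressed miRNAs.
* **Differential effects**: planted T-vs-N effects (default ±4 log2,
  alternating sign) apply to T *and* M samples — expression changes
  manifest in the primary tumor and persist in metastasis — while M-vs-T
  effects apply to M only. The ±4 default is chosen so that pipeline-feeding
  miRNAs clear the |log2FC| > 3 network threshold; calibration experiments
  override it (e.g. ±2 for SAM power runs).
* **Patient effect**: each patient's T and M samples share a per-feature
  Gaussian profile shift (default sd 1). Being independent across features,
  it produces the observed tumor/metastasis co-clustering *without*
  inducing correlation between unrelated feature pairs. Its magnitude is a
  free parameter: the reference study reports pairing fractions but nothing
  that pins the effect size down.
* **Repressions**: each planted target is `baseline - b (miRNA - mean) +
  noise` per sample (default `b = 1`, noise sd 0.5), making the planted
  correlation analytically known:
  `r = -b sd_m / sqrt(b^2 sd_m^2 + sigma^2)`. Repression is linear in log2
  space because the analysis only assumes monotone anti-correlation, and
  linearity keeps the planted `r` computable. A share of repressions is
  hosted by differential miRNAs (several targets each, so induced networks
  are populated): full slope under up-regulated hosts — a coherent,
  strongly down-shifted target group that serves as the planted perturbed
  pathway — and 0.35× slope under down-regulated hosts, diluting the
  target universe the way partially repressed targets do in real data.
* **Decoy predictions** are drawn among pairs where *neither* member
  carries a planted class effect. This is deliberate: decoys exist to
  measure the support filter's false discovery rate, and two features
  independently shifted in the same contrast are confounded — correlated
  without interacting — rather than null. Class-confounded co-expression is
  a real phenomenon and a known limitation of correlation support, but it
  is not what a calibration decoy should contain.
* **Circuits** wire a TF expression row (appended to the gene matrix) to a
  differential miRNA and a dedicated target gene with the correlation
  pattern of each circuit type; the corresponding prediction and
  interaction rows are emitted by `generate_target_predictions()` and
  `generate_tf_layer()`. **Survival** times are exponential under a
  proportional-hazards model with linear predictor `beta (x - 6)` on
  per-patient miRNA levels drawn N(6, 1), with independent exponential
  censoring calibrated to the target censoring fraction (default 0.3).

What the generator does *not* emulate: probe-level noise, batch effects,
normalization artifacts, tissue contamination mixtures, non-linear or
translational-only regulation, and correlated decoys (above). Passing the
suite therefore demonstrates that the machinery is correct and calibrated
under its own assumptions — not that those assumptions hold in any given
real dataset.

## Null-calibration conventions

Two checks run on a dedicated null configuration with the patient effect
switched off as well as all plants removed: the uniformity of correlation
p-values and SAM's false-call rate. Both procedures' null distributions
assume exchangeable samples, so their calibration is assessed under that
assumption; with the patient effect on, the handful of within-patient T/M
pairs makes both tests very slightly liberal (about 5% variance inflation
on correlations at the default effect size), which is a property of the
data structure, not of the implementations. Recovery and FDR checks —
planted repressions against decoys, planted differential features, circuit
and survival recovery — all run on the full default cohort, patient effect
included.

## Numerical choices and degenerate inputs

* Sorting and tie-breaks are deterministic throughout (stable orderings,
  first-index ties), so identical configuration and seed reproduce outputs
  byte for byte; the pipeline report is written with full precision.
* `estimate_s0` windows features into at most 100 `s`-quantile groups and
  ignores empty windows; an all-identical `s` distribution returns that
  shared value.
* Zero-variance features: the SAM statistic with `s0 = 0` and zero pooled
  variance is an error, as is correlation against a constant profile (such
  predictions are skipped and counted, not silently dropped). Set tests
  with fewer than two present members are flagged untestable rather than
  scored.
* Cox fits detect monotone likelihood via the underlying fitter's warnings
  and coefficient magnitude; Kaplan–Meier medians are `NA` when the curve
  never reaches 0.5.
* Problem sizes in the shipped tests and acceptance script are chosen for
  fast, stable calibration: 50 null cohorts of 1,000 features for SAM
  calibration (100 permutations each), 100 planted repressions against
  5,000 decoys for support recovery, 200 Cox replicates at n = 200, 1,000
  null sets for the set test, and the default 300-miRNA / 2,000-gene
  cohort for end-to-end runs.

## Known limitations

Correlation support cannot distinguish direct targeting from co-regulation;
the circuit combined p-value treats edge p-values as independent, which is
approximate because edges share profiles; the set test ignores inter-gene
correlation within a pathway; and the headline counts of any real cohort
(numbers of differential features, supported relations, circuits) depend on
external prediction and interaction databases that this package treats as
inputs, so no attempt is made to reproduce them.
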