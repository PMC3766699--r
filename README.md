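# mircircuitnet

Integrative analysis of matched microRNA and gene expression profiles across
the three tissue classes of colorectal cancer progression — normal colon
mucosa (N), primary tumor (T), and liver metastasis (M) — for researchers
studying post-transcriptional regulation in tumor development. The package
identifies differentially expressed miRNAs, filters sequence-based target
predictions down to relations supported by expression data, assembles the
regulatory networks and miRNA–transcription-factor circuits they form, tests
pathway perturbation, and screens miRNA expression for survival association.
A synthetic matched-cohort generator with planted ground truth makes every
stage testable and calibratable without any external data.

## The statistics at the core

**Differential expression** uses Significance Analysis of Microarrays (SAM):
for feature *i*, the relative difference

    d_i = (x̄_iA − x̄_iB) / (s_i + s0)

with *s_i* the pooled standard error and *s0* the fudge factor minimizing the
coefficient of variation of |d| across s-quantile windows. Observed order
statistics of *d* are compared with their expectation under label
permutations; the threshold Δ is tuned to the smallest value whose estimated
FDR — π₀ · (median permuted call count) / (observed call count) — is at or
below the target (default 0.01).

**Target support** rests on the footprint of miRNA-mediated mRNA
destabilization: a true target's expression anti-correlates with its miRNA's.
Each predicted (miRNA, gene) pair is scored by Pearson correlation *r* over
the samples assayed on both platforms, with two-sided p from
t = r·√(n−2)/√(1−r²); Benjamini–Hochberg correction runs over all performed
tests and a relation is *supported* when q ≤ 0.01 and r < 0.

**Mixed circuits** are triangular feed-forward loops over the supported
relations plus correlation-screened validated TF interactions: TF-driven
(TF→miRNA, TF→gene, miRNA⊣gene) and miRNA-driven (miRNA⊣TF, miRNA⊣gene,
TF→gene), each scored by Fisher's combination of its three edge p-values.

**Pathway perturbation** tests each gene set against the universe of
supported DEM targets with z = (mean_set − mean_all)·√|S| / sd_all on
per-gene Welch t statistics, in both directions. **Survival screening** fits
univariate Cox proportional-hazards models per miRNA (Breslow ties), with
Bonferroni control over the panel (0.05/26 ≈ 0.002 for the reference panel).

## Worked example

```r
library(mircircuitnet)

cfg       <- cohort_config(seed = 1)          # 46 patients, 78/80 samples, 77 matched
cohort    <- generate_cohort(cfg)
predictions <- generate_target_predictions(cohort$truth, cfg)

mirna_f <- filter_by_mean_signal(
  filter_mirnas_by_detection(cohort$mirna, cohort$sheet), 5)
nrow(mirna_f)
#> [1] 207          # of 300 simulated miRNAs, the rest below the signal floor

sam  <- sam_fdr(mirna_f, cohort$sheet, c("T", "N"),
                sam_config(n_permutations = 200, seed = 1))
dems <- select_dems(sam, fc_threshold = 3, background = 5)
c(called = sum(sam$results$called), dems = nrow(dems))
#> called   dems
#>     19     18  # miRNAs at FDR < 0.01; 18 also pass |log2FC|>3 + background

rel <- support_targets(mirna_f, cohort$gene, predictions,
                       sheet = cohort$sheet, q_max = 0.01)
summarize_support(rel)[c("n_relations", "n_mirnas", "n_genes")]
#> $n_relations [1] 48   $n_mirnas [1] 39   $n_genes [1] 48
attr(rel, "r_cut")
#> [1] -0.396       # least negative supported correlation, a consequence of FDR<=0.01

head(rel, 2)
#>   mirna_id   gene_id      r        p        q conserved  n
#> 1  miR_001 gene_0151 -0.984 1.88e-58 2.55e-55      TRUE 77
#> 2  miR_003 gene_0128 -0.984 1.58e-57 1.04e-54      TRUE 77

net <- induce_dem_network(rel, dems)
net
#> <regulatory_network> 45 nodes (gene: 27, miRNA: 18), 27 edges (mirna_target: 27)
```

The 48 supported relations are the planted repressions and circuit pairs the
generator wired in (recovered here in full, with roughly one decoy slipping
through at q ≤ 0.01); the induced network contains the 18 selected
differential miRNAs and their supported targets. `run_pipeline(
pipeline_config(seed = 1), "out")` executes all stages — simulation,
filtering, SAM, support, networks, circuits, pathways, survival — writing
per-stage TSVs and a `report.json` with the count funnel and truth-recovery
metrics; reruns with the same seed are byte-identical.

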