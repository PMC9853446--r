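# nksig

Derivation, refinement and application of natural killer (NK) cell gene
signatures for bulk tumour transcriptomes.

NK cells are MHC-unrestricted cytotoxic lymphocytes whose tumour
infiltration predicts better outcomes in colorectal cancer, but they are
rare in most tumours and transcriptionally close to T-cell subsets, so naive
marker lists bleed signal from other cell types. `nksig` is for
computational immunologists who need an NK marker set specific enough to
infer NK abundance from bulk RNA-seq, and an auditable record of why every
candidate gene was kept or removed. It implements:

* **Candidate collation** — GMT ingestion, per-gene source-membership
  tables, exclusive intersection counts, and the *union-DEG* criterion: a
  gene qualifies only if it is up-regulated in NK cells versus **every**
  other immune cell type within at least one reference dataset.
* **A specificity-filtration cascade** with a per-gene evidence ledger:
  immune median dominance (strict, per dataset, intersected), tumour
  cell-line filter (failures unioned across panels), stromal-compartment
  ratio filter with a paired significance gate, and single-cell
  classification into `specific` / `high_basal` / `non_specific`.
* **Rank-based single-sample scoring**: with signature size *n*<sub>s</sub>
  among *N* ranked genes,
  score = (mean rank − (*n*<sub>s</sub>+1)/2) / (*N* − *n*<sub>s</sub>) ∈
  [0, 1], invariant to any strictly increasing per-sample transform; decile
  and median stratification into NK-high / NK-low.
* **Differential expression** between strata via a variance-moderated t
  with empirical-Bayes shrinkage (prior df by moment matching on log s²),
  BH adjustment and strict DEG thresholds (|log2FC| > 1, adjusted
  p < 0.05); cross-cohort DEG overlap and Spearman logFC concordance;
  competitive rank-sum and hypergeometric enrichment tests.
* **Survival association**: Kaplan–Meier, two-group log-rank, multivariate
  Cox proportional hazards (Efron ties; adjusted for age, stage, MMR
  status), and Welch t-tests of score versus clinical parameters.
* **A synthetic-data module** generating every input type with planted
  ground truth — marker folds, leaky/stromal contaminants, latent NK
  mixing fractions, hazard ratios — so the whole workflow is testable end
  to end.

## Worked example

One call runs the full workflow on synthetic data with planted truth:

```r
library(nksig)
res <- run_pipeline(pipeline_config(seed = 1), out_dir = "nksig_demo")

length(res$signature)
#> [1] 20
table(res$ledger$final_status)
#> removed:stromal  removed:tumour        retained
#>               5               5              20
```

The generator planted 30 NK markers (fold 8), of which 5 leak into tumour
cell lines and 5 into the fibroblast compartment. The cascade recovered all
20 clean markers, removed all 10 contaminants at the correct stages, and
admitted no false positives. Scoring 100 bulk mixtures whose latent NK
fraction is uniform on [0, 0.2]:

```r
head(res$scores, 3)
#>   sample     score mean_rank n_signature_genes_used group
#> 1 MIX001 0.6462879   1290.15                     20   mid
#> 2 MIX002 0.7771970   1549.35                     20  high
#> 3 MIX003 0.7798737   1554.65                     20  high
cor(res$scores$score, res$mixture_truth$nk_fraction_per_sample,
    method = "spearman")
#> [1] 0.9207828
```

The recovered signature is strongly enriched among genes up-regulated in
score-high versus score-low samples, and the score groups separate survival
in a cohort simulated with a protective log hazard ratio of −0.7 for the
NK-high group:

```r
res$enrichment
#> Competitive set test: z = 7.689 (up), p = 1.48e-14 (n_set = 20)
res$logrank
#> Log-rank test: chi2 = 8.189 (df = 1), p = 0.004214
res$cox
#> Cox proportional-hazards fit (efron ties): n = 100, events = 66
#>    term      beta      se       z        p     hr
#> 1 group -0.990687 0.29241 -3.3880 0.000704 0.3713
#> 2   age  0.008282 0.01377  0.6015 0.547484 1.0083
#> 3 stage  0.170641 0.17792  0.9591 0.337514 1.1861
#> 4   mmr  0.708325 0.31489  2.2495 0.024483 2.0306
```

The group coefficient (hazard ratio 0.37 for NK-high, log-rank p = 0.0042)
recovers the planted protective effect; age, stage and MMR were generated
independently of the score group. Every artifact — filtration ledger,
signature GMT, scores, DEG table, survival outputs, ground truth, config
snapshot and provenance — is written under `out_dir`, and reruns with the
same configuration are byte-identical.

A ten-gene published core NK signature for colorectal cancer ships as a
fixture for scoring real matrices:

```r
sig <- read_gmt(system.file("extdata", "nk_signature_core10.gmt",
                            package = "nksig"))[[1]]
```

## Documentation

`vignettes/nk-signature-workflow.Rmd` describes the model and its
assumptions, every tunable threshold with its default and rationale, what
the synthetic generators do and do not emulate, and the package's numerical
conventions and known limitations.
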