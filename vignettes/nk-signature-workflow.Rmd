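---
title: "Deriving and applying a tumour-specific NK cell gene signature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and applying a tumour-specific NK cell gene signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nksig)
```

## The problem

Natural killer (NK) cells are cytotoxic innate lymphocytes whose infiltration
into solid tumours — colorectal cancer in particular — is associated with
better outcomes, yet they are rare in most tumours and their transcriptional
programme overlaps heavily with T-cell subsets. Inferring NK abundance from
bulk tumour RNA-seq therefore requires a marker gene set that is (i) genuinely
higher in NK cells than in *every* other immune population, (ii) not expressed
by the tumour cells themselves, (iii) not expressed by stromal, endothelial or
epithelial compartments, and (iv) still NK-specific at single-cell resolution
inside tumours. `nksig` implements that derivation as an auditable pipeline
and the downstream analyses a cohort study needs: single-sample scoring,
stratification, high-versus-low differential expression, enrichment, and
survival association. A synthetic-data module generates every input type with
planted ground truth so each stage, and the cascade as a whole, is testable.

## The derivation cascade

Candidate genes enter from two directions: published marker collections
(tracked per gene in a source-membership table, `collate_sources()`), and
pairwise differential expression of sorted immune profiles
(`pairwise_nk_degs()`). The **union-DEG criterion** (`merge_union_degs()`)
keeps a gene only if, within at least one dataset, it is up-regulated in NK
cells versus *every* other immune cell type compared there — a much stronger
requirement than winning any single pairwise contrast.

Candidates then pass four sequential specificity filters
(`apply_cascade()`), each recording its numeric evidence in a per-gene
ledger:

1. **Immune median dominance** — the NK median must strictly exceed the
   median of each other immune type; applied per reference dataset, passes
   intersected across datasets. Ties fail: specificity claims get no benefit
   of the doubt.
2. **Tumour cell lines** — a gene fails if its median across tumour lines
   exceeds its median across NK samples; failures are unioned across line
   panels, so any panel can disqualify a gene.
3. **Stromal compartments** — within each patient, expression in each
   non-leukocyte compartment (CD31+ endothelium, FAP+ fibroblasts, EpCAM+
   epithelium) is divided by the matched CD45+ leukocyte expression on the
   linear scale. A gene fails if some compartment has mean ratio above 1
   *and* a one-sided paired t-test of the log-ratios is significant at 0.05.
   The two published readings of this rule differ (a plain ratio threshold
   versus a significance requirement); we implement the ratio rule with an
   optional significance gate, default on, and record both the ratio and the
   p-value in the ledger so either convention can be audited.
4. **Single-cell classification** — per gene and cell type we compute the
   library-normalized mean and the fraction of cells expressing. A gene is
   `specific` if its NK mean is at least `ratio_cut` (default 2) times the
   largest non-NK mean and at least `frac_cut` (default 0.25) of NK cells
   express it; `non_specific` (removed) if at least `k = 2` non-NK types
   reach within `1/ratio_cut` of the NK mean; otherwise `high_basal`
   (retained but flagged). These numeric thresholds are our own declared
   conventions — the qualitative classes they encode (promiscuous expression
   across several types versus moderate basal expression in one) are
   described in the literature without exact cutoffs. Genes absent from the
   single-cell matrix are recorded as `unevaluable`, never silently dropped.

The ledger partitions candidates exactly: every gene ends `retained` or
`removed:<stage>` with the evidence that decided it. Filters are idempotent,
and adding a contaminant cell type to the immune reference can only shrink
the pass set.

## Single-sample scoring

Scoring is rank-based. Within one sample, genes are ranked ascending with
average ties, and for a signature of $n_s$ genes present among $N$ ranked
genes

$$\mathrm{score} \;=\; \frac{\overline{\mathrm{rank}} - (n_s + 1)/2}{N - n_s},$$

which is 0 when the signature occupies the bottom $n_s$ ranks, 1 at the top
$n_s$, and 0.5 in expectation under exchangeable ranks. Because only
within-sample ranks enter, the score is invariant to any strictly increasing
per-sample transform — counts, CPM, TPM and log scales all give identical
scores, so cross-platform cohorts can be scored without renormalization.
The score is an up-direction-only statistic: the derived signature is a
single "up" set, and bidirectional scoring variants are out of scope.

Stratification follows two conventions: top/bottom `floor(q*n)` samples
(`q = 0.10`) as score-high/low for differential expression, and a median
split (ties at the median going low, matching "above the median" read
strictly) for survival. Decile boundary ties are broken by stable sample
order; neither rule is standardised in the field, so both are declared
conventions here.

## Differential expression engine

Two-group contrasts use log2-CPM values (`to_log_cpm()`, pseudo-count 0.5 on
the CPM scale — a standard stabiliser, configurable) after removing genes
below 1 CPM in fewer than `min_samples` samples. Per gene, the pooled
residual variance $s^2$ on $d$ df is shrunk towards a prior $s_0^2$ with
prior df $d_0$ estimated from all genes by closed-form moment matching on
$\log s^2$ (mean and variance of $\log s^2$ identify $d_0$ through the
trigamma function, inverted by Newton iteration). The moderated t is the
mean difference over the posterior standard error on $d_0 + d$ df. If the
observed $\log s^2$ spread is no wider than a chi-square on $d$ df implies,
$d_0 = \infty$ and the test becomes a pooled-variance z-like test; with
fewer than 10 informative genes the moment fit is unstable and we fall back
to $d_0 = 10$. Precision weighting against the mean–variance trend is
deliberately omitted: the moderated t on filtered log-CPM is the engine, and
its null calibration on overdispersed counts is verified by simulation in
the test suite. DEGs use the strict thresholds |log2FC| > 1 and BH-adjusted
p < 0.05.

Enrichment uses two deliberately simple tests: a competitive rank-sum z
(normal approximation with tie correction, no continuity correction and no
inter-gene correlation inflation — a conservative simplification of
correlation-adjusted competitive tests, adequate for synthetic data where
genes are independent by construction) and a one-sided hypergeometric
over-representation test against a user-supplied term-to-gene-set map in GMT
form, so no ontology download is needed.

## Survival modelling

Kaplan–Meier curves, the two-group log-rank test and multivariate Cox
proportional-hazards fits are delegated to the `survival` package behind a
clinical-record contract (positive times, 0/1 events, `high`/`low` groups
encoded with high = 1 so the reported log hazard ratio refers to the
high-score group). Ties use the Efron method by default (Breslow available);
Newton–Raphson runs to `eps = 1e-9` within 50 iterations, and suspiciously
large or non-finite coefficients are flagged as possible separation. Age
enters in years, stage as ordinal 1–3 and MMR status as binary, without
standardisation — coefficients are therefore unit-dependent, which is
documented rather than hidden. Score-versus-clinical-parameter comparisons
use the Welch t-test.

## What the synthetic generators emulate

`synth_config()` fixes one set of study conditions shared by all
generators: 2000 genes with log-normal baseline means (meanlog `log(50)`,
sdlog 1.2), negative-binomial counts with dispersion 0.1, bulk library sizes
log-normal around $10^7$ (sdlog 0.2) and single-cell libraries around
$10^4$ (sdlog 0.3) — depths different enough that CPM normalization matters.
Seven immune cell types with four replicates each carry 30 planted NK
markers at linear fold 8, of which 5 are additionally "leaky" into tumour
cell lines (fold 10) and 5 into the fibroblast compartment (fold 5).
The baseline sdlog of 1.2 keeps gene-abundance heterogeneity realistic while
keeping the compositional side-effect of planting (markers inflate the NK
library total, shrinking observed CPM fold-changes) a second-order
correction. Dropout in single-cell mode is independent Bernoulli zeroing —
the simplest mechanism sufficient for specificity-classification tests.
Mixtures are convex combinations of the NK and pooled non-NK mean profiles
with NB noise; survival cohorts use exponential event times with the hazard
multiplied by $e^{\beta}$ for the high group and independent exponential
censoring whose rate targets the requested censoring fraction approximately
(the two groups have different event hazards, so the realised fraction
deviates slightly). Covariates are independent of the score group unless a
confounding coefficient is switched on. Setting `dispersion = 0` switches
every generator to noise-free expected values, which the exactness oracles
in the tests exploit.

What they do **not** emulate: batch effects, doublets, cell-cycle or spatial
structure, correlated gene modules, platform-specific biases, or informative
censoring. Passing tests therefore demonstrate that the machinery is correct
and calibrated under its stated model, not that the recovered signature on
real cohorts would match any published gene list — reproducing a specific
published signature requires the original public cohorts, which this package
deliberately does not download. A ten-gene published core signature for
colorectal cancer ships as a GMT fixture
(`system.file("extdata", "nk_signature_core10.gmt", package = "nksig")`)
for use as a realistic scoring input.

## Problem sizes and numerical conventions

The bundled end-to-end configuration (`pipeline_config()`) uses 2000 genes,
7 × 4 sorted immune samples, 20 cell lines, 6 compartment patients, 420
single cells, 100 mixtures with NK fractions uniform on [0, 0.2], and a
100-subject survival cohort with planted log hazard ratio −0.7 (protective,
matching the direction expected for NK infiltration) and ~20% censoring; it
runs in seconds and is the configuration exercised by the acceptance checks.
Calibration simulations use 2000 genes at 10 vs 10 replicates (type-I
error), 100 planted genes at linear fold 4 (power/FDR), and 500-subject
cohorts over 50 replicates (hazard-ratio recovery). These sizes were chosen
as the smallest at which the binomial and sampling tolerances of the
corresponding checks are meaningful.

Numerical conventions collected in one place: strict inequalities at every
published threshold (a log2FC of exactly 1 is not a DEG; a tied median is
not specific); BH adjustment via the standard step-up with capping at 1;
ratios in the stromal filter take a pseudo-expression of 0.5 in numerator
and denominator to stay finite at zero counts; score-boundary and
median-tie rules as above; duplicate gene identifiers on input collapse to
the row with the largest total, with a warning; gene symbols are uppercased,
whitespace-stripped and truncated at `|`, with no alias or ortholog
resolution — cross-species use relies on case-normalized symbol matching
only.

## Worked example

```{r example, eval = FALSE}
library(nksig)

res <- run_pipeline(pipeline_config(seed = 1), out_dir = "nksig_demo")

# planted-truth audit
truth <- res$truth
mean(truth$planted_nk_markers %in% res$signature)
res$ledger[res$ledger$final_status != "retained", c("gene", "final_status")]

# score fidelity against the latent NK fraction
cor(res$scores$score, res$mixture_truth$nk_fraction_per_sample,
    method = "spearman")

# survival association of the recovered signature
res$logrank
res$cox
```

Every artifact (ledger, signature GMT, scores, DEG table, survival outputs,
ground truth, configuration snapshot and provenance record) is written under
`out_dir`; reruns with the same configuration are byte-identical.

## Known limitations

* The cascade's contaminant filters are strict-median rules: a planted
  contaminant whose off-target expression lands marginally below the NK
  reference level can survive by construction. This is the intended
  behaviour of the published rule, not a defect of the implementation.
* The competitive enrichment test ignores inter-gene correlation and will be
  anticonservative on real (correlated) expression data; it is exact for the
  independent-gene synthetic model.
* The DE engine handles two-group contrasts only — no design matrices,
  duplicate-correlation or array weights.
* Hypergeometric p-values are discrete; calibration checks treat them as a
  near-continuous mixture by varying set sizes.
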