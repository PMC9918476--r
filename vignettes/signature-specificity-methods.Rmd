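---
title: "Auditing the tissue-compartment specificity of bulk transcriptomic signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing the tissue-compartment specificity of bulk transcriptomic signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigaudit)
```

## The question the package answers

A gene signature derived from bulk tumor profiles is only useful as a
*tumor* subtype label if its expression originates in neoplastic cells.
Bulk pancreatic tumor samples are mixtures of tumor epithelium, residual
acinar tissue, immune infiltrate and fibroblast stroma, and several
published pancreatic subtype signatures behave like purity meters: their
scores rise as neoplastic cellularity falls. `sigaudit` operationalizes the
audit that distinguishes tumor-intrinsic signatures from
contamination-driven ones, using four independent lines of evidence —
purity correlation, cross-tissue contrasts, paired primary/model-system
retention, and gene-level decomposition of the signature itself.

## Scoring model

The score of sample $i$ for gene set $G$ is the arithmetic mean of log2
expression over the set's genes present in the data,

$$ s_i = \frac{1}{|G \cap D|} \sum_{g \in G \cap D} x_{gi}, $$

with coverage $|G \cap D|/|G|$ reported and a warning below 50% (low
coverage degrades interpretability; gene-level subsets of a signature can
behave very differently from the whole). For panels that compare tissue
types on one axis the scores are mean-centered and scaled,
$z_i = (s_i - \bar s)/\mathrm{sd}(s)$ with the $n-1$ denominator.
Standardized scores are cohort-dependent by construction, so every result
that uses them records the standardization cohort; subsetting the cohort
changes the values, and the tests assert exactly that. Scores are defined
on log2 data only — `to_log2()` applies $\log_2(x + c)$ with a recorded
pseudocount (default $c = 1$) and refuses to transform twice.

## Rank statistics

Both headline statistics are implemented in the package (they are part of
its contract) and cross-checked in the tests against base R and brute-force
enumeration:

* **Spearman correlation.** Average ranks for ties; $\rho$ is the Pearson
  correlation of the rank vectors; the two-sided p uses
  $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ df. $|\rho| = 1$ is reported
  as $p = 0$ with a degeneracy flag. Pairs with a missing value are dropped
  pairwise and counted, never imputed.
* **Wilcoxon rank-sum.** The Mann–Whitney $U$ of the first group. With at
  most 10 observations per group the null is obtained by exact enumeration
  of all $\binom{n_a+n_b}{n_a}$ splits of the observed pooled values — a
  conditional permutation test, which handles cross-group ties exactly and
  makes two identical groups yield $p = 1$. Larger groups use the normal
  approximation with tie correction and a continuity correction. The
  two-sided p is $P(|U - n_an_b/2| \ge |u_{obs} - n_an_b/2|)$, which is
  symmetric under swapping the groups.

## Consensus clustering

The resampled k-means consensus procedure is implemented from scratch. Per
resample, $\lceil f n \rceil$ items are drawn without replacement
($f = 0.8$ by default), k-means with k-means++ seeding, Euclidean distance,
10 restarts and the best within-cluster sum of squares partitions the
subsample, and co-cluster and co-sampling tallies accumulate. The consensus
matrix is the elementwise ratio; the final partition is the average-linkage
hierarchical cut of $1 - M$ into $k$ groups (the standard convention for
this procedure family; a PAM-style alternative could be swapped behind the
same interface). Defaults: 1000 resamples for production use (the tests use
20–250, which is where the consensus matrices already stabilize on the
problem sizes below), Lloyd iterations capped at 300. Lloyd's algorithm
stops when assignments are stable, which subsumes a numeric tolerance. One
master seed drives a deterministic substream per resample, so runs are
reproducible and resample rounds are order-independent.

Two applications share the engine:

* **Sample subtyping** (`assign_subtypes`): rows restricted to the union of
  the collection's genes, $k$ = number of gene sets. Gene rows are
  centered/scaled before clustering (otherwise Euclidean distance is
  dominated by high-magnitude genes; a flag disables this, and whether the
  original analyses scaled is genuinely open — the default is documented,
  not asserted as anyone's practice). Clusters are then named by gene set:
  each cluster takes the set with the highest mean standardized score among
  its members, assigned one-to-one greedily in decreasing order of each
  cluster's score margin, ties broken by collection order.
* **Signature decomposition** (`decompose_signature`): items are the
  signature's genes, features the samples. The per-cluster mean expression
  by tissue type lets the caller label gene clusters (acinar-specific,
  nonspecific, ...) — the gene-level anatomy of a confounded signature.

## The verdict rules

A signature is called `non_tumor` when its score is significantly
negatively purity-correlated ($\rho \le -0.1$, $p < 0.05$) **or** its
cell-line mean is significantly below the primary mean with a negative
paired loss; `tumor_intrinsic` when retention holds (no significant
cell-line loss) and the purity correlation is above the threshold;
`ambiguous` otherwise, including when evidence is missing. The thresholds
are configuration, not constants — the underlying findings are directional,
so every report echoes the rules it applied, and verdicts are deterministic
functions of the evidence fragment plus rules.

## What the generator emulates, and what it does not

Each synthetic sample's linear-scale expression is
$p_i\,T(s_i) + \sum_c w_{ci}\,C(c)$ with $p_i + \sum_c w_{ci} = 1$,
observed as $\log_2(x+1) + \varepsilon$, $\varepsilon \sim N(0,
\sigma^2)$ on the log2 scale (multiplicative noise on the linear scale is
the standard bulk-expression approximation). The gene universe is organized
in compartment blocks (40 genes each by default, 200 background genes);
elevated genes sit $\delta$ log2 units above the baseline of 3 log2 units
($\delta = 1.5$ by default, a strong but realistic bulk signature effect).

Key structural choices, all fixed before any result was computed:

* **Purity prior** Beta(5, 3) for primaries and metastases — right-shifted,
  mimicking resected-tumor cellularity; acinar cell carcinomas use
  Beta(9, 1) (high-purity tumors whose neoplastic profile is acinar-like,
  which is exactly why they confound acinar signatures).
* **Contamination split** over (acinar, immune, CAF) is Dirichlet(2, 2, 3),
  slightly stroma-weighted as in real PDAC; compartment weights in real
  tumors are not quantified anywhere, so these are plausibility choices and
  are labeled as such in the truth output.
* **Per-tumor signature strength** $s \sim \mathrm{LogNormal}(0, 0.2)$
  multiplies the tumor-block elevation and is inherited by derived cell
  lines and metastases. This is the tumor-intrinsic heterogeneity that
  makes paired retention informative: primaries express their subtype
  signature at high or low levels, and their derived models track those
  levels.
* **Deliberately impure gene lists.** The ADEX-like list is the acinar
  block plus 20 nonspecific background genes (so gene-based decomposition
  has a real mixture to separate); the immunogenic list carries ~13%
  tumor-classical genes (6 of 46), reproducing the tumor-gene contamination
  of published immune signatures — visible as `gene_list_overlap` counts
  and as partial cell-line retention.
* **Tissue rules.** Cell lines are pure tumor; PDXs carry a residual 0.05
  CAF weight; CAF lines are pure fibroblast; normal pancreas is
  (0.85, 0.10, 0.05) over (acinar, immune, CAF); metastases carry
  non-pancreas background contamination; non-pancreas normals are
  background-dominated with modest immune/CAF weight.
* **Seeding.** One master seed, one counter-based substream per sample
  (with disjoint counter ranges per tissue type), so enlarging one tissue
  group never perturbs the samples already generated.

What the generator does **not** model: read-level sequencing noise, UMI
counts, platform/batch effects, copy-number dosage, probe-level microarray
structure, or single-cell resolution. Passing tests therefore demonstrate
that the statistical machinery recovers compartment structure from
purity-weighted mixtures under realistic noise — they do not certify any
particular real dataset, where alignment, normalization and annotation
issues add failure modes the mixtures cannot produce.

## Numerical and interface choices

* Genes are rows, samples are columns, everywhere; nothing transposes
  implicitly.
* Writers emit full-precision (`%.17g`) UTF-8/LF text so write→read round
  trips are bit-exact; readers reject ragged rows, duplicate identifiers
  and non-numeric cells by name.
* Gene identifiers match by exact case-sensitive equality; no alias or
  probe collapsing (one row per gene is assumed and documented).
* Missing metadata is an explicit `NA`, never an empty string; filtering
  clauses never match missing values.
* Standardization errors out on zero variance rather than returning silent
  zeros; the robustness panel records such sets as failures. For a pure
  housekeeping set the standardized tissue spread is noise-floor limited
  (group means of order $1/\sqrt{n_g}$), which is why the tests compare it
  to compartment sets rather than to zero.
* The rank-sum exact path is used whenever both groups are ≤ 10; because
  it is a permutation test conditional on the observed values, it is valid
  with or without ties.
* TSP prediction ties: within-pair equal values vote 0.5; a vote fraction
  exactly at the threshold calls class 2, so predictions are deterministic
  and invariant under strictly increasing transforms.
* No multiple-testing correction by default (raw two-sided p-values are
  reported, matching how such contrasts are usually presented); a
  Benjamini–Hochberg flag is available on the contrast panel.

## Problem sizes

The default simulated cohort is 150 primaries, 25 cell lines, 25
metastases, 15 PDXs, 15 normal pancreata, 10 CAF lines, 10 non-pancreas
normals and 6 ACCs over 440 genes — large enough that purity confounding,
retention and decomposition are unambiguous, small enough that the full
test suite (including 100-seed replicate sweeps) runs in about a minute.
Consensus runs in the tests use 20–250 resamples; the analytic slope helper
integrates with $2 \times 10^5$ deterministic draws.

## Limitations

The verdict rules are intentionally simple threshold logic over four
statistics; they do not model dependence between lines of evidence. The
classifier is a generic top-scoring-pairs engine with majority voting — it
deliberately omits fitted pair weights, so it demonstrates the
cohort-independence property rather than reproducing any published
classifier's exact calls. The consensus implementation selects $k$ from the
number of gene sets by design and offers no automatic $k$ selection.
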