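---
title: "Inferring miRNA-target transcript networks from paired expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring miRNA-target transcript networks from paired expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirtarnet)
```

## The analysis problem

miRNAs fine-tune gene expression by guiding the RNA-induced silencing
complex to complementary sites in target mRNAs, promoting transcript decay
or blocking translation. When a miRNA rises in a disease state, its targets
are expected to fall. `mirtarnet` implements the integrative workflow that
exploits this expectation in paired miRNA-seq and RNA-seq data from the
same tissue (the motivating setting is duodenal biopsies in celiac
disease, but nothing in the package is tissue-specific):

1. **Differential expression** of each layer between cases and controls,
   adjusting for covariates such as age and sex.
2. **Candidate pairing**: restrict a union of public miRNA-target databases
   (prediction tools and experimentally validated collections) to pairs
   whose miRNA and gene are both differentially expressed.
3. **Anticorrelation filtering**: keep a candidate pair as a network edge
   only when the Pearson correlation of the two transformed expression
   profiles is strongly negative (`r < -0.7`) with `p < 0.05`.
4. **Network reporting**: bipartite summary statistics, a
   degree-versus-correlation comparison, and prioritization of transcripts
   targeted by at least two miRNAs with experimental support.
5. **Over-representation analysis** of network targets against a gene-set
   collection, globally, split by fold-change direction, and per miRNA.
6. **Cell-type composition**: single-sample enrichment scores for
   atlas-derived cell-type miRNA signatures, their group differences and
   correlations, and a composition-corrected differential expression model.

Because biopsy-scale studies are small and the reference databases are
external, the package ships a synthetic-data generator that emulates all
five inputs with planted ground truth, so every stage can be validated
end to end.

## Differential expression model

Counts for feature *f* in sample *s* are modelled as negative binomial,

$$y_{fs} \sim \mathrm{NB}(\mu_{fs}, \alpha_f), \qquad
  \log \mu_{fs} = \log c_s + x_s^\top \beta_f,$$

with median-of-ratios size factors $c_s$ as offsets and a design matrix
containing the covariates and the case/control indicator. The reported
effect is the log2 fold change (case vs control); the Wald statistic
$\beta/\mathrm{se}(\beta)$ is referred to the standard normal and
Benjamini–Hochberg adjusted across tested features.

Deliberate simplifications relative to shrinkage-based DE packages:

* **Dispersion** is a per-feature method-of-moments estimate on normalized
  counts, $\hat\alpha = \max\{(\hat v - \hat m)/\hat m^2,\, 10^{-8}\}$,
  held fixed during the fit. There is no Cox–Reid adjustment, no shrinkage
  toward a mean–dispersion trend, and no outlier replacement. At the
  sample sizes the package targets for validation (tens of samples per
  group) the Wald test is calibrated within a few percent of nominal,
  which the test suite checks directly; at very small *n* per group the
  test will be somewhat liberal, as for any fixed-dispersion Wald test.
* **No LFC shrinkage**: raw maximum-likelihood log2 fold changes are
  reported.
* **Independent filtering** by base mean is available
  (`filter_quantile`) but off by default, so the BH family is exactly the
  set of features with nonzero base mean and a converged fit.
* Features whose fit fails or is degenerate are reported `tested = FALSE`
  with missing statistics and are excluded from the BH denominator,
  never silently dropped.

The **regularized-log-like transform** used for correlations, PCA and
signature scoring is `log2(count / size_factor + 1)` — a monotone,
variance-limiting pseudo-log, not a shrinkage-based regularized log. It is
named `rlog_like()` to make the distinction visible.

## Edge admission

For each candidate pair the product-moment correlation is computed over
the samples assayed on **both** layers (statuses pooled: the pooled
between-group signal is precisely what makes repression visible at small
*n*), with the two-sided p-value from
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom. Both admission
inequalities are strict (`r < -0.7`, `p < 0.05`); a pair sitting exactly
at a threshold is rejected. The direction requirement is already imposed
by the correlation threshold, so a two-sided p-value is used. Pairs are
deduplicated across database sources with provenance union; a pair counts
as experimentally validated if *any* contributing source is a
validated-class database.

For the degree comparison, each transcript is summarized by the
arithmetic mean of its edge correlations by default (`aggregate =
"pooled"` pools edges directly instead; per-transcript aggregation is
not standardized in the field, so both are provided). The
two-sided Mann–Whitney U test enumerates the exact null when both classes
have at most 8 members (ties included); otherwise it uses the
tie-corrected normal approximation without continuity correction.

## Over-representation analysis

Enrichment of a query (network targets, a direction subset, or one
miRNA's targets) in a gene set uses the upper-tail hypergeometric mass
within a background of expressed genes — the mRNA dataset, not the
genome, following standard ORA practice for tissue data. FDR is computed
within each query's result list, matching per-figure reporting. Tools
disagree on whether "GeneRatio" means hits over query size (k/n) or hits
over set size (k/K), so both `gene_ratio_kn` and `gene_ratio_kK` are
emitted rather than guessing. Semantic term-redundancy reduction is out of
scope; `collapse_redundant_sets()` offers a clearly-labelled greedy
Jaccard collapse (threshold 0.5, keep best p) as an approximate stand-in.

## Cell-type signatures and composition correction

Signatures are the top-`k` (default 10) miRNAs per cell type by atlas
enrichment, ties broken lexicographically. The single-sample score is an
ssGSEA-style running sum: features are ranked within a sample
(descending, average ranks for ties) and the score is the maximum
deviation between the rank-weighted in-set cumulative distribution
(weights $(N - \mathrm{rank} + 1)^\tau$, default $\tau = 0.25$) and the
uniform out-of-set step. Comparable workflows usually reach for GSVA,
whose method space (gsva/ssgsea/zscore) is broad; the running-sum score
implemented here was chosen because it is fully specified in this
document, rank-only (invariant to monotone within-sample transforms),
and hand-checkable at $\tau = 0$. It is a GSVA-family substitute, not a
GSVA reimplementation. Scores are not rescaled across samples.

`corrected_de()` appends the signature scores as continuous covariates
and refits the NB model. A miRNA whose case/control difference is carried
by cell-type composition loses significance; a direct regulatory effect
survives. Constant or collinear score columns are an error (silently
dropping them would make "corrected" and "uncorrected" coincide without
warning). xCell-style compendium scoring is out of scope; the same
`ss_enrichment()` operation applied to RNA data with caller-supplied
marker sets is the provided substitute and is not xCell.

## The synthetic-data generator

Each sample draws cell-type proportions $w_s$ from a status-specific
Dirichlet; each feature has per-cell-type log2 baselines $b_{fc}$ and a
latent abundance $x_{fs} = \sum_c w_{sc} b_{fc} + \delta_f\,
\mathbb{1}[\text{case}]$. For a planted pair $(m, g)$ the gene's latent
mean is reduced by $\beta\,(x_{ms} - \bar x_m)$ — repression acts on the
latent scale, before noise, so the induced anticorrelation is tunable.
Counts are NB draws around $\ell_s 2^{x_{fs}}$ with log-normal library
sizes.

Default conditions (chosen once as a realistic biopsy-scale study, and
deliberately not calibrated to any particular deposited dataset, whose
library sizes and dispersions are not published):

* 10 controls + 10 cases by default; validation scenarios state their own
  sizes (n = 24 for network recovery, 20 + 20 for composition analyses,
  50 + 50 for the latent-correlation check).
* 100 miRNAs, 500 genes; baselines Uniform(4, 9) and Uniform(3, 8) log2,
  so typical counts are tens to hundreds.
* NB dispersion 0.05, library-size log-SD 0.2.
* Three compartments (epithelial, T cell, other) with Dirichlet
  concentrations (6, 2, 2) in controls and (4, 4, 2) in cases — lower
  epithelial and higher T-cell fractions in cases, the confounding
  pattern the composition stage is built to detect. Ten marker miRNAs
  per compartment are elevated by 3 log2 units in their own cell type and
  carry **no** direct status effect: their observed DE is purely
  composition-driven.
* 40 planted pairs; pair miRNAs carry direct status effects of ±1.5 log2
  with alternating sign, target genes carry none (their DE is induced).
  A further 10% of each layer receives direct effects (±1.5 miRNA,
  ±0.8 gene), again sign-balanced so normalization stays identifiable.
* Age ~ Uniform(2, 17) years and sex ~ Bernoulli(0.5), a pediatric cohort
  shape; neither influences expression, they exercise the covariate
  machinery.
* The database lists each true pair in each prediction source with
  probability 0.9 and each validated source with probability 0.5, and
  adds 4 unique decoy pairs per true pair, subject to the same
  source-level sensitivities.

What the generator does **not** emulate: sequencing-depth-dependent
mean–variance trends, correlated gene modules beyond the low-dimensional
composition structure, isomiRs, batch effects, or genotype-dependent
targeting. Passing the recovery tests therefore demonstrates that the
pipeline's logic is correct under its own assumptions, not that any
particular biological dataset would yield the same networks.

## Numerical choices

* Strict inequalities at both edge-admission thresholds; boundary pairs
  rejected.
* Dispersion floor $10^{-8}$ keeps the NB family defined for
  zero-variance features.
* BH missing-value semantics: `NA` p-values stay `NA` and leave the
  denominator.
* Constant expression vectors: skipped (with a message) in correlation
  contexts, an error where a correlation is the deliverable
  (`lfc_atlas_correlation`).
* Signature ties at the top-`k` cut are resolved lexicographically and
  reported.
* Exact Mann–Whitney enumeration only up to group size 8
  (12,870 assignments at 8 + 8); beyond that the tie-corrected normal
  approximation is used.
* All simulation entry points are deterministic in `seed`; the database
  and fixture generators use fixed offsets of the dataset seed so the
  three artifacts are jointly reproducible yet draw independent streams.

## Validation problem sizes

The shipped test-suite scenarios use: 2,200 null feature fits at
30 + 30 for Wald calibration; 1,000 random ORA queries against 10 sets of
60 in a 2,000-gene background; 200 planted log2-unit effects among 1,000
features at 60 + 60 for effect recovery; ten simulations at 12 + 12 with
a 4:1 decoy database for network precision/recall; and fifty simulations
at 20 + 20 for the composition-correction contrast. These sizes make the
whole suite run in minutes on one core while leaving each check's
sampling error well inside its acceptance margin.

## Known limitations

* The Wald test with fixed method-of-moments dispersion is approximate at
  very small group sizes; a likelihood-ratio test or dispersion shrinkage
  would be the next step for n per group below ~6.
* Identifiability of fold changes relies on most features being null (a
  property of median-of-ratios normalization); designs where a large,
  direction-imbalanced fraction of the transcriptome shifts will alias
  part of the shift into the size factors.
* Gene identifiers are opaque strings; harmonizing miRNA accessions and
  gene symbols across databases is the caller's responsibility.
* The package reports networks and statistics; interactive visualization
  is delegated to GraphML consumers.
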