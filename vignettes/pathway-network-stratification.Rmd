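---
title: "Pathway-driven stratification and key driver analysis: methods and design"
author: "StratNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-driven stratification and key driver analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

StratNet implements an integrated analysis of merged case/control
transcriptomes of the kind used to characterize inflamed glandular tissue
in autoimmune disease: several microarray datasets are merged at the
gene level, normalized and batch-corrected, screened for differentially
expressed genes (DEGs), projected onto a protein-protein interactome, and
summarized per patient as pathway enrichment scores that drive
unsupervised subgrouping, a subgroup classifier, and key driver analysis
(KDA) on a directed gene network.

Every stage is exercised end to end on a synthetic-data generator that
reproduces the statistical structure the analysis assumes, so the whole
pipeline is testable without external downloads.

```{r, eval = FALSE}
library(StratNet)
res <- runPipeline(syntheticConfig(seed = 1), seed = 1)
```

# Preprocessing

**Quantile normalization** forces identical empirical distributions across
samples by rank-wise substitution of the row-mean reference distribution;
tied values receive the mean reference value over their rank span. The
operation is idempotent and delegated to `limma::normalizeQuantiles`.

**Batch correction** (`combatAdjust`) is the parametric empirical-Bayes
location-scale model: genes are standardized with the case/control factor
protected in the design (so biological signal is not absorbed into the
batch term), per-batch location and scale estimates are shrunk toward
batch-level prior moments (normal prior for location; inverse-gamma by
method of moments for scale), and the data are back-transformed. Two
points were genuinely open and decided here:

* whether the group factor is protected inside the standardization —
  it is, because the case/control imbalance across source datasets would
  otherwise bleed biological differences into the batch estimates;
* the `mean-only` mode removes the *raw* per-batch location estimate
  (plain per-gene centering, scale untouched). This makes corrected
  per-gene batch means equalize exactly, which is the behavior a user
  asking for a location-only adjustment expects; the EB-shrunk location
  estimate would leave per-gene residuals by construction. The default
  `location-scale` mode keeps the full EB shrinkage.

Zero-variance genes are floored at `1e-8` with a warning. `pcaQC`
reports component scores, variance explained and per-component R² of the
batch and group factors; on corrected data the batch R² of the leading
component should collapse (in the bundled synthetic default it falls from
~0.94 to ~0.001).

# Differential expression

The two-group moderated-t workflow: per-gene ordinary linear models
(log2 fold change, pooled residual variance on *n* − 2 df), an
empirical-Bayes variance prior estimated by method of moments on
`e = log s² − ψ(d/2) + log(d/2)` with the prior df obtained by inverting
the trigamma function, posterior variances
`s̃² = (d₀s₀² + d·s²)/(d₀ + d)`, and two-sided t tests on `d₀ + d` df
with Benjamini-Hochberg control. `d₀ = 0` recovers the ordinary pooled t
exactly and `d₀ = ∞` uses the normal reference; in the infinite-d₀
branch the prior variance is `exp(ē)` (the geometric-mean-based moment
estimate). The full covariate machinery of general linear modeling is
deliberately reduced to the single case/control contrast the pipeline
uses; batch is handled upstream by `combatAdjust`, not inside the gene
models. The DEG filter defaults to adjusted *P* < 0.01, with the
upregulated list feeding the network stages.

# Interactome analysis

Upregulated DEGs are projected onto the interactome; the induced
subgraph's components, largest connected component (LCC) and
centralities are computed with igraph. Design choices:

* **harmonic closeness** (sum of reciprocal distances) instead of
  classical closeness, because the DEG-induced graph is typically
  disconnected and classical closeness is undefined across components;
* **hub molecules** are the nodes shared by the top-10% ranks of degree,
  closeness and betweenness. The cutoff is `ceiling(fraction · n)`
  computed over the whole induced network by default (a flag restricts
  ranking to the LCC); a value tie straddling the cutoff admits all tied
  nodes, favoring reproducibility over exact set size.

# Enrichment

`fisherORA` is the one-sided hypergeometric over-representation test
with a Haldane-corrected odds ratio. `gseaES` is the weighted
running-sum statistic with exponent default *p* = 1 (the classic
weighted form; *p* = 0 reduces to the rank Kolmogorov-Smirnov statistic)
and leading-edge extraction at the peak. The permutation null draws
random same-size gene sets rather than permuting phenotypes, because the
subgroup sizes at this scale are too small for phenotype permutation to
have resolution; p-values use the add-one estimator.

`ssgseaScore` ranks one sample's genes by expression (average ranks on
ties, residual ties broken by gene identifier), weights in-set positions
by `rank^α` (default α = 0.25, α = 0 supported for rank-only scoring)
and sums the difference between the weighted in-set ECDF and the uniform
out-of-set ECDF over all positions. Scores are reported as raw sums;
min-max normalization across the matrix is available but off by default,
since the clustering stage z-scores per pathway anyway. The enrichment
map connects gene sets whose Jaccard similarity strictly exceeds 0.25.

# Subgrouping, statistics, classification

Clustering operates on the pathway × sample score matrix transposed to
samples × pathways with each pathway z-scored, so no pathway dominates by
scale. Agglomerative UPGMA (average linkage) on Euclidean distances is
the default; the cluster number is chosen over k = 2–5 by the gap
statistic (uniform reference over the PCA-aligned bounding box,
`s_k = sd·√(1 + 1/B)`, smallest k with `Gap(k) ≥ Gap(k+1) − s_{k+1}`),
with mean silhouette reported per k as the agreement check. Average
linkage was preferred over Ward because the score profiles are low
dimensional and the subgroup geometry is elongated rather than
spherical; t-SNE confirmation plots are intentionally out of scope —
`pcaQC` scores serve as the low-dimensional visual check.

Between-cluster comparisons use the unpaired t or Mann-Whitney U test
with BH adjustment; paired designs (two timepoints) use the paired t,
with the degenerate all-zero-difference case defined as t = 0, p = 1.
Categorical associations use chi-squared with an expected-count check
and Fisher fallback; continuous associations use Pearson correlation.

The subgroup classifier is Gaussian naive Bayes over the pathway panel:
class priors from training frequencies, per-class per-feature normal
densities, variances floored at `1e-9 ×` the feature's global variance
to prevent likelihood spikes when a feature is constant within a class.
Validation uses stratified 10-fold cross-validation with deterministic
folds under a seed; models serialize to JSON.

# Key driver analysis

KDA takes a target gene set *G* and a directed (acyclic) gene network.
The candidate pool is the subnetwork of nodes within *H* layers of *G*,
searched in both edge orientations so upstream regulators are included.
For each candidate *g* and depth *h* = 1…*H*, the *h*-layer downstream
neighborhood (BFS over child edges, excluding *g*) is tested for
enrichment in *G* by a one-sided Fisher test against all other network
nodes, with *g* excluded from its own neighborhood, target set, and
background. The enrichment statistic is `ES = −log10 p`, so maximizing
ES over layers coincides with minimizing p; ties go to the smallest
depth. Key drivers are candidates with Bonferroni-corrected p (m = the
number of tested candidates, not the network size) below 0.01; drivers
with no parents are *global*, the rest *local*. Defaults decided here:
*H* = 3 (configurable 1–6), downstream neighborhoods (drivers regulate
what is below them; an undirected mode exists because "layers away" is
direction-agnostic in common usage).

# The synthetic generator

`syntheticConfig()` defines the emulated study: 30 cases vs 23 controls
from 4 source batches over 2,000 genes (a desk-scale stand-in for a
~17,500-gene merged cohort), additive Gaussian structure on the log2
scale matching post-summarization microarray convention:

* per-gene baselines N(7, 1); per-gene-per-batch shifts N(0, 0.3);
  measurement noise N(0, 0.5);
* 150 signed DE genes at |log2 FC| = 1 (half up by default) — effect
  magnitudes for the real contrasts are never published, so defaults
  were chosen once as plausible microarray effect sizes, and the planted
  recovery experiments state their own conditions explicitly;
* two latent case subgroups expressed as +1 log2 shifts on the member
  genes of each subgroup's active pathways (5 + 5 of a 26-pathway
  panel), matching the pathway-level nature of real patient subgroups;
* a preferential-attachment interactome over the full gene universe with
  a planted clique over 15 upregulated DE genes. The module is drawn
  from *upregulated* DE genes deliberately: the network stages analyze
  the upregulated list, and a module straddling both directions would
  dissolve at DEG selection;
* a layered DAG in which each planted driver is a root directly
  parenting its share of the target set (the planted module first), each
  layer-1 target parents exactly one further target plus one filler
  child, and filler nodes form an independent random DAG. Drivers are
  therefore strongly target-enriched at depth ≤ 2, internal target nodes
  are not, and non-adjacent roots are never enriched.

One master seed fans out to fixed per-component streams, so regenerating
one component never shifts another's draws and equal configurations give
byte-identical files.

**What passing tests do not show.** The generator is additive, Gaussian
and homoscedastic; real merged microarray cohorts have intensity-dependent
variance, correlated genes, probe-mapping artifacts and batch effects
that are not purely location-scale. Recovery rates on this generator
validate the machinery, not the biology of any particular cohort.

# Numerical choices and problem sizes

Variance floors: `1e-8` (batch model, degenerate genes), `1e-12`
(posterior variances), `1e-9 ×` global feature variance (classifier).
The trigamma inverse uses Newton iteration to `1e-10` relative change.
BH ties in DEG ordering are broken by gene identifier.

The validation suite sizes its simulations for interactive runtimes:
exhaustive Fisher enumeration over all tables with margins ≤ 12;
centrality/LCC oracles over all 4-node graphs and random 5–7-node
graphs; KDA oracles over random DAGs ≤ 10 nodes; calibration at 2,000
null genes and 200 replicates; recovery at G = 5,000 (variance prior),
20 seeds (clustering), 50 seeds (classifier permutation and planted-driver
recovery on 200-node networks). The full double pipeline run used for the
determinism check completes in well under a minute on one CPU.

# Known limitations

* Starts from gene-level log2 matrices; probe-level summarization and
  cross-platform probe mapping are out of scope.
* Nonparametric batch priors and missing-value imputation are not
  implemented.
* Cell-type inference is approximated as ssGSEA over user-supplied
  signature collections; trained signature compendia and spillover
  compensation are out of scope.
* The directed network is an input; learning its structure from
  expression is out of scope.
* No t-SNE embedding; use the PCA scores for visual confirmation.
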