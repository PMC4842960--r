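---
title: "panomap: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{panomap: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panomap)
```

# The model

`panomap` performs hybrid early/intermediate integration of same-sample
multi-omic measurements. The working assumption is that biologically
meaningful sample structure (subtypes, tissue identity) expresses itself as
*local* similarity — samples of a kind sit near each other — in some or all
of the molecular data types, and that each type's contribution should be
weighted equally a priori rather than by its feature count or raw variance.

The pipeline is: per-type normalization to a comparable scale, per-type PCA
to strip feature-level noise and reduce each platform to the same number of
coordinates, variance balancing so no platform dominates, concatenation,
and a non-linear 2D embedding (t-SNE) that preserves local neighbourhoods
at the expense of global geometry. Every downstream statistic — density
clustering, label enrichment, out-of-tissue calls, contribution profiles —
reads structure off that map or compares maps with each other, so the
quality of the map is itself measured (rank-based local-similarity score,
cophenetic agreement with the pre-embedding space, nearest-neighbour label
AUC, rerun stability).

## Per-type normalization

* **GE / MIR** (non-negative abundance units): `log2(v + 1)`, then per-gene
  zero-mean. The pseudocount avoids infinities at zero counts.
* **CN** (gene copy numbers, diploid = 2): `log2(v / 2)`, then per-gene
  zero-mean, so diploid maps to 0 and gains/losses are symmetric in log
  space.
* **ME** (beta values in [0, 1]): probe betas are averaged gene-wise over
  probes within 1,500 bp of the transcription start site (probes at
  exactly the window edge are included; 1,501 bp is out), then samples are
  quantile-normalized to a common distribution, per-gene centered, and the
  reconstruction from the leading principal component is subtracted.
* **All types**: genes on chromosomes X and Y are removed before analysis
  so sex does not masquerade as biology; features missing in every sample
  are dropped; remaining missing cells are imputed from the K = 3 nearest
  samples.

Centering is idempotent (re-centering changes nothing within 1e-8), which
the tests assert directly.

### Choices the normalization required

* **ME principal-component removal count.** How many leading components
  represent "technical variation" is genuinely open; the package default is
  `removePCs = 1` — the smallest intervention that implements the idea —
  configurable, with 0 disabling the step. With fewer than
  `removePCs + 1` samples the step is refused.
* **Quantile-normalization reference.** The mean of the per-sample sorted
  vectors, ties averaged (`limma::normalizeQuantiles`), the standard
  construction.
* **Imputation distance.** Root-mean-square Euclidean distance over
  features observed in both samples — i.e. scaled by the number of shared
  observed features, so samples with different missingness patterns remain
  comparable. Donors must themselves observe the target feature.
  Zero-distance donors (exact duplicates on the shared features) take
  precedence over the K-nearest mean: a duplicated sample inherits its
  twin's values exactly.
* **Missing-cell markers** in delimited input files: empty string or `NA`.

## Reduction, balancing, embedding

`reduceBlock()` retains the top 50 principal components per type by
default; `retainVariance = 0.95` instead keeps the smallest set of leading
components explaining 95% of the variance. Requests beyond the rank bound
`min(samples − 1, features)` are refused with the admissible maximum
(the cohort-level wrapper `integrateCohort()` caps silently, since a small
cohort should not abort a standard run).

`scaleBlock()` divides scores by the square root of the block's total
retained variance. After scaling, every block's summed component variance
is exactly 1 (tested to 1e-6) regardless of whether the platform measured
60 or 20,000 features — this is the precise sense in which "no data type
dominates". Blocks are concatenated in the fixed order GE, ME, CN, MIR so
the integrated matrix is byte-reproducible.

The embedding is an exact-gradient t-SNE written for this package in
C++ (RcppArmadillo): Gaussian input affinities calibrated per sample to
the target perplexity by 50 bisection steps, symmetrized and floored at
1e-12; Student-t output kernel; gradient descent with learning rate 200,
early exaggeration 12 for the first min(250, maxIter/3) iterations,
momentum 0.5 switching to 0.8 at the same point; adaptive per-coordinate
gains (±0.2 / ×0.8, floored at 0.01); initial coordinates drawn
N(0, 1e-4). O(n²) per iteration is the right regime for cohort-scale maps
(hundreds to a few thousand samples); the final Kullback–Leibler
divergence is evaluated on the unexaggerated objective and reported on the
map object.

Restarts use seeds `seed, seed + 1, …` (a deterministic fan-out, so a
1000-restart selection is reproducible), and the restart with the lowest
KL divergence wins. With a fixed seed and one restart the embedding is
bitwise reproducible on the same platform build; across BLAS builds the
usual floating-point caveats apply.

**Perplexity** is not dictated by the method; the default is 30, and
`n / 10` (minimum 2) for cohorts under 100 samples. For very small maps
(a few dozen samples, e.g. an out-of-tissue isolation rerun) low
perplexities can fragment clusters; such runs accept an explicit
`perplexity` argument and around 8–12 behaves well in the packaged tests.
Iteration count (default 1000) and learning rate are exposed but rarely
worth touching.

## Comparing maps

The local-similarity score between maps X and Y over the same samples is

$$s_{x,y}(k_x,k_y)=\frac{1}{n\,\min(k_x,k_y)}\sum_i\sum_{j\neq i}
\mathbf 1\!\left[r^x_{ij}\le k_x \wedge r^y_{ij}\le k_y\right]$$

with $r^x_{ij}$ the rank of $j$ among $i$'s distances in X (nearest = 1;
ties broken by ascending sample index so ranks are deterministic). The
score lives on [0, 1]; equals 1 exactly when each sample's $k_x$ nearest
neighbours in X are contained in its $k_y$ nearest in Y or vice versa; is
symmetric under $(X,k_x)\leftrightarrow(Y,k_y)$; and its expectation under
independent random maps with $k_x=k_y=k$ is $k/(n-1)$. **A note on
provenance:** the published description of this score is partly
illegible in the source text available to this package (the equation
bodies are images); the form above is the package's documented
reconstruction, chosen as the unique min-normalized joint-neighbourhood
count that reproduces every property the surrounding prose states. Tests
verify the score against a brute-force double loop for all n ≤ 12 and all
admissible neighbourhood sizes.

`tissueCohesionTest()` asks whether same-label samples sit closer than
random subsets of the same size (statistic: mean pairwise within-label
distance; p by the add-one permutation estimator, never exactly 0).
`nnLabelAUC()` reports a macro-averaged one-vs-rest AUC over per-sample
margins `d(nearest other-class) − d(nearest same-class)`; the multiclass
construction is not canonical anywhere, so the result carries its own
description in `$construction`. `copheneticComparison()` builds Ward
trees on both representations and correlates their cophenetic distances.

## Clustering the map and out-of-tissue calls

DBSCAN is used because map structure is density-shaped, not spherical.
`minSamples` defaults to 5 (a conventional value; the protocol leaves it
open). The radius `eps` is selected by scanning a grid — default 50
log-spaced values between the 1st and 50th percentile of pairwise
distances — and keeping, among values that yield at least two clusters
and at most 10% non-clustering samples, the one maximizing the mean
silhouette of clustered samples; exact ties go to the smaller radius. Two
consequences are worth knowing. First, because the silhouette is computed
on clustered samples only, the selection may prefer shaving a few boundary
points into noise (within the cap) over including them — with a coarse
grid of generous radii this does not arise. Second, a Davies–Bouldin
index is reported alongside in the scan diagnostics (`$grid`), since that
index is sometimes preferred for choosing cluster numbers; the silhouette
rule is the operative one here, the Davies–Bouldin column is diagnostic
only.

Cluster–label association is the upper-tail hypergeometric test at
α = 0.001. A sample is a **COP** ("cancer outside primary") when its own
tissue is not among its cluster's significantly enriched labels.
Non-clustering samples are COPs by definition and are attributed to the
nearest cluster centroid for subtyping. COP-I: the (attributed) cluster
has at least one enriched label — the sample sits in another tissue's
territory. COP-II candidate: the cluster matches no tissue. With ten or
more COPs, `dissectCOP2()` reruns the full pipeline on the COPs alone and
confirms type II for isolation clusters with no enriched tissue;
non-clustering samples of the rerun keep their prior candidate call. The
membership-in-enriched-cluster rule is this package's operationalization —
the original protocol's exact decision rule (distance threshold versus
membership) is not published.

## Contribution analysis and stability

For T data types there are `2^T − 2` proper non-empty combinations — 14
for four — enumerated in a canonical order (singletons, pairs, triples;
within size, lexicographic in the GE, ME, CN, MIR order). Each
combination is embedded with the same restart budget and perplexity as
the reference full map (each with its own seed fan-out) so comparisons
are like-for-like. Per sample and combination, the overlap percentage
`100·|NN_k(combination) ∩ NN_k(full)| / k` (k = 20 by default, matching
the smallest-tissue heuristic) fills the profile matrix; mean overlap per
column equals 100× the local-similarity score at `kx = ky = k`, a
cross-module identity the tests assert. Ward clustering of profile rows
yields genomic profiles; the number of profiles defaults to 5 but is a
free parameter. `mapStability()` re-embeds the full combination with
seeds `seed+1 … seed+nRuns` and flags samples whose mean k-NN overlap
with the reference falls below a threshold — 20% by default; the
threshold behind any published "no consistent neighbourhood" count is not
stated anywhere, so it is exposed prominently rather than buried.

## Outcome statistics

Survival uses the standard machinery (`survival`): Kaplan–Meier
product-limit curves, the log-rank test with p from the χ² tail on
(groups − 1) df, and Cox proportional hazards with **Breslow** tie
handling (the simplest well-defined choice; recorded on the output).
Non-convergence or complete separation is an error, not a silent NA.
Annotation comparisons: Mann–Whitney U for continuous, one-sided Fisher
exact for categorical. Gene-set enrichment: upper-tail hypergeometric
against any GMT collection with Benjamini–Yekutieli adjustment (valid
under arbitrary dependence between overlapping sets), selection at
adjusted p < 0.05; the default background is the measured gene universe
passed by the caller, not the genome. Differential expression is a
per-gene **Welch test with Holm correction** — a deliberate, labelled
substitution for the moderated-variance model used in the original
analysis, preserving the pipeline contract (gene lists in, corrected
calls out) without re-implementing an external empirical-Bayes model;
zero-variance genes get p = 1 rather than NaN. Co-expression networks
keep edges with |r| > 0.6 — the absolute value is intended, since the
published networks display both positive and negative edges — and prune
nodes below 2 partners to a fixed point; modules are connected components
(the original 4-cluster partition method being unstated).

# The synthetic-data generator

`generateCohort()` emulates exactly the features the pipeline's claims
depend on: multiple latent clusters whose separation is planted only in
configurable driver types (non-driver types share a common center);
type-appropriate marginals (GE/MIR ≥ 0 via `2^(baseline + signal) − 1`,
ME in (0, 1) via a logistic squash, CN > 0 near diploid via
`2·2^(0.3·signal)`); sex-linked X/Y features (5% of features, +2 latent
shift in males) so the sex-filter step has something to remove; missing
cells at 2% by default; planted COPs that copy the target cluster's
latent signal in **every** type while keeping the source tissue label
(mirroring the observation that the most robust out-of-tissue samples are
detected across all combinations); and per-cluster exponential survival
with uniform censoring, for analytic transparency.

Default scale — 3 clusters × 50 samples, features GE 300 / ME 200 /
CN 200 / MIR 60, effect size 4 within-cluster SDs — is a deliberate
desk-scale miniature: large enough that 50 components per type and
20-neighbourhoods are meaningful, small enough that a full 15-map
contribution analysis runs in seconds. Feature counts keep the real-world
ordering (expression-like platforms widest, miRNA narrowest). Effect size
4 represents clearly separated subtypes; the effect-size sweep
{0, 1, 2, 4} in the tests shows recovery rising monotonically from chance
to ARI > 0.9.

What the generator does **not** emulate — and therefore what passing
tests do not certify about real data: realistic gene–gene covariance
(features are independent given cluster), platform batch effects beyond a
single removable component, heavy-tailed count noise, informative
missingness, competing risks, or the sample-size regime of real
consortium data. Headline numbers published for a 4,434-sample cohort
(cluster counts, similarity percentages, survival p-values) are
properties of that data and are not reproduced by simulation here; the
package instead certifies the machinery's correctness (oracle
equivalence, calibration, parameter recovery) at sizes stated below.

# Numerical choices and degenerate inputs

* Rank ties → ascending sample index; eps-grid ties → smaller eps;
  block order fixed; restart seeds deterministic. Everything about a run
  is reproducible from (spec, seed).
* Affinity floor 1e-12 in t-SNE; KL reported on the renormalized plain
  objective.
* Permutation p-values use the add-one estimator: the smallest
  attainable p is 1/(nPerm + 1).
* Degenerate inputs fail loudly and early: duplicate IDs (named),
  non-rectangular tables, all-missing samples (named), empty sample
  intersections, zero-variance blocks, perplexity ≥ n/3, k ≥ n,
  single-label AUC, zero-event survival. Warn-and-continue is reserved
  for recoverable cases: unannotated features in the sex filter,
  singleton labels in the cohesion test, fewer than 10 COPs for the
  isolation rerun.

# Problem sizes used by the packaged checks

The test suite runs cohorts of 60–150 samples (20–50 per cluster, three
clusters), 30–500 features per type, embeddings of 250–600 iterations
with 1–3 restarts, 300-point clustering fixtures, 20-replicate null
calibrations and 999-permutation cohesion tests — sizes chosen so the
full suite exercises every module deeply in about two minutes on one
core. All thresholds asserted by the tests (ARI ≥ 0.9 at effect 4,
noise cap 10%, oracle tolerances 1e-6 … 1e-12) are stated in the test
files themselves.

# Known limitations

* Exact t-SNE is quadratic in samples; beyond ~5,000 samples a
  tree-approximate backend would be preferable.
* The silhouette-under-noise-cap selection compares silhouettes computed
  on different clustered subsets; see the clustering section for the
  boundary-shaving consequence.
* The local-similarity score is a reconstruction (see above), albeit one
  pinned down by every published property of the measure.
* Multiclass AUC and the map-stability consistency threshold are
  package conventions, recorded on their outputs.
* The ME pipeline treats one gene-level matrix as one platform; separate
  per-beadchip handling beyond TSS-averaging + quantile normalization is
  not modelled.
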