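---
title: "Methods behind atlaskit: models, thresholds and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind atlaskit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atlaskit)
```

`atlaskit` implements the statistical procedures specific to building and
using a large, multi-dataset single-cell atlas. This vignette explains
each procedure, the assumptions behind it, the tunable parameters and
their defaults, what the synthetic-data generator does and does not
emulate, and the numerical choices made where the design was genuinely
open. No empirical claim is made here that the package's test suite and
`scripts/acceptance.R` do not themselves compute.

## The setting

The input is a collection of scRNA-seq datasets: raw count matrices with
per-cell metadata (dataset, donor, sample, the generator's original cell
label) and per-sample metadata (anatomical location, age, sex, BMI,
smoking status), plus a low-dimensional integrated embedding of all cells
(by convention 30 dimensions; how that embedding is produced — scANVI,
Harmony, anything — is outside this package's scope). The package's own
data container is `atlas_table`: a sparse cells × genes count matrix plus
the two metadata tables, written to disk as MatrixMarket + TSV.

## Preprocessing and harmonization

**Cell/gene filters.** Cells with fewer than 200 detected genes
(count > 0) are removed, then genes detected in fewer than 10 cells
(`filter_cells_genes()`). The two passes interact — removing cells can
push a gene below threshold — so a `fixed_point = TRUE` variant iterates
to convergence; the single-pass order (cells first) is the default
because it matches the order the filters are conventionally stated in.
"Expressed/detected" means count > 0 throughout the package; no alternative
threshold is used anywhere.

**Size-factor screening.** Externally estimated size factors (e.g. from
pooling-based normalization) are screened, not estimated: cells with
factors below 0.01 or with normalized totals above 10^6 are dropped
(`screen_size_factors()`). These bounds flag degenerate estimates, not
biology.

**Gene-name harmonization.** Identifiers from different annotation
releases form a weighted graph (`gene_name_graph()`): nodes are
identifiers, edges are matchings, and a matching's similarity *s* becomes
the edge weight 1 − *s* + ε (unscored matchings get 0.5), so
better-supported links cost less. For each source identifier the simple
path to any target-namespace node with the lowest *mean* edge weight is
selected (`harmonize_gene_names()`); ties break by shorter path, then
lexicographic target. Mean rather than summed weight means a long chain
of perfect matchings beats one poor direct link, which is the desired
behaviour across annotation releases. Parallel matchings between the same
pair of identifiers collapse to the best-supported one. Sources mapping
to a common target are returned grouped, and `sum_collided_genes()` sums
their columns, conserving per-cell totals exactly. Path enumeration is
exhaustive; identifier graphs are shallow and sparse, and the test suite
checks agreement with an independent enumeration oracle on random graphs.

**Label harmonization.** Cell identities live in a five-level hierarchy
(`label_tree()`): level 1 holds the coarsest compartments (epithelial,
immune, endothelial, stromal), level 5 the finest states. Each dataset
maps its original labels onto tree nodes; `harmonize_labels()` expands
the mapped node into its full ancestor chain, leaving levels below the
node as `"none"`. This makes datasets annotated at different depths
comparable level by level, which everything downstream (entropy QC,
calibration, markers) relies on.

## Anatomical common coordinate

`raw_coordinate()` encodes sampling location on a single
proximal-to-distal axis: upper-airway landmarks at 0, 0.5, 1.0, 1.5, 2.0;
trachea at 2.5 continuing the same increment; airway generation *g* at
2.5 + log2(*g*) with the trachea as generation 1 of an assumed 23; the
alveolar sac takes the generation-23 value (≈ 7.02). `ccf_score()`
rescales by the alveolar value so the axis runs 0 → 1. The log base is
exactly 2 and full precision is kept internally; rounding happens only in
reports. Tokens outside the canonical vocabulary (e.g. "parenchyma") are
deliberately not hard-coded to a generation; `ccf_table()` accepts a
user-supplied mapping for them, since any specific generation would be a
guess.

## Cluster quality control

**Nested clustering.** `nested_cluster()` builds a kNN graph (exact
Euclidean neighbours, undirected union, unit weights) and partitions it
with Leiden community detection; level 1 uses k = 30 at resolution 0.01
on all cells, levels 2–5 recompute the graph within each parent cluster
with k = 30, 15, 10, 10 at resolution 0.2. Children are numbered by
decreasing size, giving dot-separated ids ("1.2" is the third biggest
subcluster of cluster 1). Clusters smaller than k + 1 are left unsplit.
The community-detection seed is explicit, and the partition is
deterministic given it.

**Entropy scores.** Label disagreement and donor diversity are both
natural-log Shannon entropies of within-cluster proportions
(`shannon_entropy()`, `cluster_entropies()`). Cells unlabeled at the
evaluated level are excluded, and the label entropy is reported `NA` when
fewer than 20% of a cluster's cells are labeled. Thresholds come from
hypothetical reference clusters (`entropy_thresholds()`): a 75/25 label
split gives 0.56 (above = high disagreement), and 95% dominance by one of
107 donors gives 0.43 (below = donor-dominated). The natural log is not a
free choice: with log2 those constructions give 0.81 and 0.62, so the
published threshold values pin the base, and a test asserts this.

**Doublet candidates.** Clusters that combine high level-1 label entropy,
small size (default ≤ 1% of cells) and simultaneous expression of two or
more top-level lineage marker modules are flagged
(`flag_doublet_clusters()`). "Simultaneous expression" is operationalized
as the cluster's mean module expression reaching at least 25% of the
maximal cluster's for that module. Doublets formed by averaging two
parents sit near half the pure level, comfortably above this bar, while
cross-lineage leakage in pure clusters stays far below it. A
mean-centred score was rejected: halving a highly expressed module can
land *below* the atlas mean when the parent lineage is abundant, which
silently misses exactly the doublets the flag is for. The flag is a
candidate list for review, not a verdict.

**Rare types and external label sets.** `rare_type_pr()` reports, per
cluster, recall (share of all rare-labeled cells captured) and precision
(share of the cluster that is rare-labeled). For annotations absent from
the reference (e.g. spatially derived types in a mapped dataset),
`recover_labelset_cluster()` scans Leiden resolutions 0.1–100 (k = 30
below resolution 25, k = 15 at or above, so tiny clusters become
resolvable), keeps clusters with recall and precision both ≥ 25%, and
selects by: highest recall, unless that costs more than a third of the
runner-up's precision; a runner-up that doubles precision while losing at
most 20% recall wins outright.

## Label transfer and calibration

`knn_transfer()` assigns each query cell the label with the largest
weighted proportion among its k = 50 nearest reference neighbours in the
joint embedding, with uncertainty u = 1 − that proportion. Weights use a
Gaussian kernel exp(−(d/d_k)²) with per-cell bandwidth equal to the k-th
neighbour distance — a documented choice (the transfer convention this
follows does not fix a kernel), with an unweighted fallback
(`weighted = FALSE`). Ties break by summed weight at full precision, then
lexicographically, so results are deterministic. Neighbours are always
reference cells; distances are computed in the joint embedding.

`apply_unknown_cutoff()` masks transfers with u above a cutoff as
`unknown` — the mechanism by which novel or disease-shifted states
surface. `calibrate_cutoff()` chooses the cutoff from query data with
trusted annotations: incorrect transfers are the positives, "u > t" the
prediction, and the ROC over all observed thresholds is summarized by the
Youden point (max TPR − FPR) subject to FPR < 0.5. Only cells annotated
at hierarchy levels 3–4 enter: coarser levels are uninformative, and
level-5 disagreements reflect annotation granularity rather than transfer
failure. When every transfer is correct the ROC is degenerate and no
cutoff is returned, with a warning.

## Marker genes from pseudo-bulks

Statistics are computed on per-(sample, cell type) pseudo-bulk mean
expression profiles, so every sample — not every cell — carries one vote,
and sample-to-sample consistency is what is tested. A pseudo-bulk
requires ≥ 10 cells, relaxed to ≥ 3 for types with fewer than 100 cells
atlas-wide (`build_pseudobulks()`). As means of many draws, pseudo-bulk
values are treated as approximately normal and compared with Welch's
*t*-test (`marker_ttest()`), vectorized across genes and cross-checked
against `stats::t.test` in the suite.

Significantly upregulated genes (BH FDR < 0.05, positive fold change — the
alpha follows the package-wide convention) then pass three fraction
filters (`filter_markers()`): expressed (pseudo-bulk mean > 0) in ≥ 80% of
the type's pseudo-bulks; expressed in ≥ 50% of cells per pseudo-bulk on
average (cell fractions from raw counts > 0); expressed in ≤ 20% of all
other pseudo-bulks in the scope. `hierarchical_markers()` escalates the
reference scope for types with no survivors: full atlas (iteration 1),
the type's compartment (2), the next-coarsest subtree (3), then the same
two scopes with loosened thresholds (iterations 4–5; defaults
0.6/0.4/0.3 and 0.5/0.25/0.4). The loosened values are package defaults
exposed in `iterations =`; they are deliberate choices, not published
constants, and each marker set records the iteration and scope that
produced it. A type failing all iterations returns an empty set flagged
for manual curation. Note one property of the published filter worth
knowing: a marker planted on a *parent* type shared by exactly two
sibling leaves can legitimately pass the ≤ 20% rule for both siblings, so
sibling marker sets are exclusive only in their type-specific genes.

## Covariate variance attribution

`pc_regression()` implements the share of embedding variance a covariate
explains: per component, ordinary least squares of the scores on the
(dummy-encoded) covariate, summing explained variances and dividing by
total variance. Regressions include an intercept (the standard OLS
formulation; the source procedure leaves this implicit). The statistic is
invariant to affine rescaling of the covariate and to component order,
equals 1 for a covariate regressed on itself, and for pure noise has
expectation ≈ (number of dummy columns)/(n − 1) — the small-sample
inflation that motivates the masking rules below.

`shuffle_null_split()` decides whether a technical covariate (chemistry
version, processing site) constitutes a batch: the observed PC_expl is
compared with 10 random reassignments, and the study is split when it
exceeds the null mean by 1.5 null SDs. With 10 shuffles this rule's
nominal false-split level is somewhat above 5% — the validation suite
measures it at ≈ 5–10% over 100 null seeds, which is the cost of the
small shuffle count the procedure specifies.

`covariate_dependence()` quantifies confounding between covariates: for a
continuous member, the square root of the variance explained by the
other (equal to |Pearson r| for two continuous variables; the continuous
variable is always the response); for two categoricals with more than two
levels each, normalized mutual information (arithmetic normalization);
for two binaries, |φ| via dummy regression.

`encode_covariates()` applies the fixed encodings: smoking never/former/
current → 0/0.5/1; nasal indicator; age scaled so 25 → 0 and 64 → 1; BMI
so 21.32 → 0 and 36.86 → 1 (10th/90th percentile anchors of the source
cohort, configurable); CCF score passed through. `vif_screen()` excludes
a cell type from gene-level modeling when any covariate's variance
inflation factor 1/(1 − R²) exceeds 5; perfect collinearity reports Inf.
The gene-level mixed model itself (expression ~ covariates + (1|dataset))
is deliberately not reimplemented — the package emits the encoded design;
fitting belongs to dedicated mixed-model tooling.

`variance_report()` runs PC regression per cell type on per-sample mean
embedding coordinates (samples with < 10 cells of the type excluded) and
masks entries with fewer than 40 covariate-annotated samples
(`insufficient_samples`) or a single observed value (`single_valued`);
below ~40 samples the explained fractions correlate spuriously with
sample count.

## Disease-state discovery

Cells of a transferred type are stratified by uncertainty: u < 0.2
(low) versus u > 0.4 (high), middle excluded (`uncertainty_strata()`).
These strata bounds are intentionally independent of the unknown-masking
cutoff — the two serve different purposes and are configured separately.
`signature_genes()` compares strata per gene with a Wilcoxon rank-sum
test (normal approximation with tie correction, cross-checked against
`stats::wilcox.test`), drops genes at BH-adjusted p > 0.05 or with mean
expression < 0.1 in the high stratum, and returns the 20 largest
log-fold-change genes. `score_cells()` turns a signature into a per-cell
score: genes are binned by atlas-wide mean expression (default 25 bins),
50 control genes per signature gene are drawn from the matching bin, and
the score is the signature mean minus the control mean — magnitude-
controlled, seeded, and ≈ 0 in expectation for random sets.

For cross-dataset cluster analyses, `cluster_de_filtered()` normalizes to
7,666 counts per cell (a fixed convention from the source cohort's median
total), log-transforms, tests a cluster against the rest and keeps genes
expressed in ≥ 30% of the cluster, ≤ 20% outside, at BH p ≤ 0.05.
`exclude_single_donor_clusters()` removes clusters whose donor entropy
falls strictly below the donor-dominance threshold before any such
analysis (a cluster exactly at the threshold is kept).

## The synthetic atlas generator

`simulate_atlas()` produces the structure every stage assumes, with
ground truth recorded for all of it:

- **Counts**: gamma–Poisson (negative binomial) with per-gene dispersion;
  per-leaf log-mean programs built hierarchically (each tree node boosts
  its own gene block in all descendant leaves: 5 genes per node, planted
  from a near-silent baseline to mean ≈ 3 for leaf blocks, ≈ 2 for
  internal blocks); dataset batch shifts (log-normal, SD 0.15) and donor
  random effects (SD 0.08).
- **Hierarchy**: a 5-level, 4-compartment lung-like tree of 20 leaves at
  depths 3–5, including a rare type at frequency 8 × 10⁻⁴; frequencies
  are validated to sum to 1, and a rare type whose expected count falls
  below one cell is emitted as zero cells with a warning.
- **Covariate modules**: donor covariates (age ~ U(20, 80), BMI ~
  U(18, 40), sex, smoking, CCF anchor locations) drive log-linear gene
  modules and a matching latent-space direction in designated leaves
  (defaults: an age module in AT2, a smoking module in secretory cells) —
  the planted signal `variance_report()` must attribute.
- **Doublets** (1%): arithmetic means of two profiles from *different*
  compartments, re-Poissonized, placed midway in latent space, carrying
  one parent's label — the population `flag_doublet_clusters()` targets.
- **Embedding**: true latent factors — hierarchical node directions with
  per-level scales plus within-type noise (SD 0.5) — optionally plus
  per-dataset offsets (`embed_batch_sd`), so both well- and
  poorly-integrated regimes are producible. The default is
  well-integrated; the batch-monotonicity property is checked on a PCA of
  the counts, where batch strength provably lands.
- **Disease states** (`simulate_query()`): a stated fraction of query
  cells of a base leaf (default alveolar fibroblasts) is displaced
  halfway toward a density-matched neighbouring type (adventitial
  fibroblasts) and given a 10-gene program whose strength scales with
  the cell's realized position along that axis — a severity continuum.
  The coupling matters: in a 30-dimensional embedding, distances
  concentrate, so neighbourhoods mix only for cells genuinely in the
  overlap zone; cells whose noise kept them near the healthy centroid
  both stay low-uncertainty *and* express little program, exactly as a
  biological continuum would. Displacement raises mean uncertainty
  monotonically up to the midpoint; past it, cells enter the
  neighbouring type's territory and purify again — so validation grids
  stay at or below the midpoint.

What the generator does **not** emulate: ambient RNA, empty droplets,
UMI saturation, spliced/unspliced layers, realistic gene–gene
correlation beyond module structure, cell-cycle effects, or an embedding
learned from the counts (latent factors are generative, not inferred).
Consequently, passing tests demonstrate the *procedures* are correct and
sensitive under the assumed noise model — not that any particular real
dataset satisfies those assumptions.

## Problem sizes, determinism and limitations

The validation suite runs the generator at 8 datasets × 6 donors × 250
cells (12,000 cells, 800 genes) for recovery checks — chosen as the
smallest scale at which every planted signal is comfortably detectable —
and smaller configurations for unit fixtures. All randomness flows from
explicit seeds: the generator is byte-identical under a fixed seed, and
the end-to-end pipeline (`run_pipeline()`) writes a manifest of MD5
content hashes that reproduces exactly across reruns.

Known limitations: exact kNN search is quadratic (fine to ~10⁵ cells;
swap in an ANN index beyond that); gene-graph path enumeration is
exponential in pathological dense graphs (identifier graphs are not);
Leiden resolution scans in `recover_labelset_cluster()` recluster the
full embedding per resolution; and the Wilcoxon normal approximation is
inaccurate for strata under ~10 cells, where the stratified signature
test is underpowered anyway.
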