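---
title: "Methods: spectral-count differential abundance and co-abundance networks"
author: "spcnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral-count differential abundance and co-abundance networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical
machinery: the models and their assumptions, the parameters that
matter, what the synthetic generator does and does not emulate, and
the numerical choices made where the design was genuinely open.

## 1. Data model

The raw input is a protein × sample matrix of spectral counts, with a
length (amino-acid residues) per protein and a phenotype label per
sample.  The canonical design is four groups — disease and healthy,
each with and without a dietary intervention (CKD, CKDRS, HRS, H) —
with four biological replicates each, i.e. 16 samples.  Counts are
nonnegative integers, strongly right-skewed, and overdispersed
relative to Poisson.

Two parallel quantification tracks are kept deliberately separate:

* the **protein track** (NSAF → log2 → imputation) produces
  continuous per-protein abundances for clustering and heatmaps;
* the **taxon track** keeps raw summed counts, because the
  differential tests and the network operate on counts and
  count-specific normalization.

### NSAF and imputation

`compute_nsaf()` divides each count by the protein length and rescales
each sample to sum to one; columns are therefore compositional
(each sample's NSAF vector sums to 1 by construction).  Zeros are
treated as *missing*, not as measured zeros: shotgun proteomics has a
detection limit, and absence of spectra for a low-abundance protein is
censoring.  `log2_transform_impute()` implements the standard
downshifted-Gaussian imputation: per sample, missing values are drawn
from a normal with mean `m − downshift·s` and SD `width·s`, where `m`
and `s` are the observed log2 mean and SD.  Defaults `downshift = 1.8`
and `width = 0.3` (in observed-SD units) are the imputation tool's
long-standing defaults for label-free data; they place imputed values
in the lower tail, where censored proteins plausibly live.  A sample
with fewer than three observed values is rejected — its moments cannot
be estimated.  No pseudocount route is offered: imputation, not
offsetting, is the modelled mechanism.

### Taxon aggregation and filtering

`aggregate_to_taxa()` sums protein counts per taxon at the protein's
*lowest assigned rank*.  A protein identified only at genus level
contributes to a genus-level taxon that is kept distinct from any
species of that genus; merging them would double-count the genus-level
evidence into one arbitrary species.  The low-count filter retains a
taxon only if it reaches `min_count = 5` spectra in at least
`min_samples = 2` samples.  This is the strict reading of "fewer than
five counts in all samples but one is removed": a single high sample
cannot rescue a taxon, which guards against one-off identification
artifacts.  The filter is idempotent and order-independent.

### TMM normalization

`tmm_normalize()` implements trimmed-mean-of-M-values scaling exactly
as published for RNA-seq: per-taxon log ratios M and log-averages A
against a reference sample (the one whose upper-quartile count
fraction is closest to the mean), computed over taxa nonzero in both
samples, doubly trimmed (30% on M, 5% on A), combined by a
precision-weighted mean with inverse asymptotic binomial variance
weights.  The composition factors (`$tmm`) agree with the reference
RNA-seq implementation to 1e-10 in the test suite.

One design choice deserves emphasis.  The returned `$factors` used
downstream are **effective** scales: relative library size × TMM
composition factor, rescaled to geometric mean one.  Downstream stages
divide counts by these factors, so a sample sequenced twice as deep
gets a factor twice as large (up to the geometric-mean rescaling), and
two identical samples get factors of exactly one.  Composition-only
factors would leave depth differences in the "normalized" counts and
corrupt the mean comparisons; this is the only convention under which
"rescale, then test" is coherent.  Scale equivariance (multiplying one
sample by c multiplies its factor by c, up to rescaling) is verified
on generated data.

## 2. Poisson–Tweedie differential abundance

The PT family is indexed by mean μ, dispersion φ = Var/μ ≥ 1 and shape
a; its named special cases are Poisson (a = 1, φ = 1), negative
binomial (a = 0, gamma–Poisson mixture) and Poisson–inverse-Gaussian
(a = ½, inverse-Gaussian–Poisson mixture).  These three cases span the
mean–variance behaviours the test must handle — equidispersion,
gamma-tailed overdispersion, and heavier inverse-Gaussian-tailed
overdispersion — so the full continuous-a family is not fit.

`fit_pt_moments()` estimates μ and φ by the method of moments on
rescaled counts (φ clamped at 1; a zero-variance vector is the Poisson
limit), then picks a by comparing the closed-form NB and PIG
log-likelihoods at the moment estimates (ties go to NB).  The PIG pmf
is evaluated through modified Bessel functions of the second kind at
half-integer order via an upward recurrence carried entirely in log
space; the direct `besselK` overflows at orders a few hundred, which
real spectral counts reach.

`pt_two_sample_test()` compares group means with

    z = (m̂_A − m̂_B) / sqrt(φ̂_A m̂_A/n_A + φ̂_B m̂_B/n_B),

the variance plug-in being max(sample variance, mean) per group — the
PT variance with φ clamped at its Poisson floor.  Degenerate inputs
are defined, not errored: both groups all-zero gives p = 1; one group
all-zero gets a variance floor of one count so the statistic stays
finite.

**Small-sample calibration.**  With n = 4 per group the plug-in
variance is itself noisy, and referring z to the standard normal is
anticonservative (empirical type-I ≈ 0.07–0.09 at nominal 0.05 under
an NB null in our simulations).  The package therefore takes the
two-sided p-value from a Student t reference with `n_A + n_B − 2`
degrees of freedom.  This coincides with the normal tail as group
sizes grow and brings the empirical size at n = 4 to ≈ 0.03–0.04 (the
acceptance suite measures it under the NB null, 2000 replicates).
Under a Poisson null the test is conservative (empirical size well
below nominal), because the variance floor max(var, mean) can only
inflate the denominator when counts are equidispersed; we accept lower
power there in exchange for never being anticonservative.

All six pairwise comparisons of the four phenotypes are tested;
BH correction is applied *within* each comparison (six separate
families), since hit lists are reported per comparison.  The union of
taxa significant anywhere is the node set for the network stage.  The
log2 fold change column adds 0.5 to each normalized group mean purely
to keep the reported table finite; the statistic uses no pseudocount.

Auxiliary tests follow field conventions: term enrichment is the
one-sided hypergeometric (Fisher exact) tail at raw p < 0.01 with no
multiplicity correction, annotations taken as flat term sets; hub
abundance contrasts are Welch t-tests; heatmap clustering is
Euclidean/complete linkage on z-scaled rows (constant rows dropped
with a warning), deterministic under R's `hclust` tie handling.

## 3. Mutual-information network inference

### MI estimation

`estimate_mi()` uses equal-frequency binning with `ceiling(sqrt(n))`
bins per variable (4 bins at the study's n = 16), plug-in MI in bits,
and the Miller–Madow bias correction, clamped at zero.  Equal-
frequency binning makes the estimate a function of ranks only, so MI
is invariant to monotone transforms — raw, TMM-rescaled and
log-transformed abundances give identical values, which removes an
arbitrary preprocessing choice from the network stage.  Ties are
broken by original sample order, making the estimate deterministic.

A caveat documented rather than hidden: the Miller–Madow correction
removes the plug-in bias only in the dense regime (n ≫ bins²).  At 16
samples and 4 bins the *absolute* null MI is far from zero — which is
exactly why C3NET judges significance against a permutation null of
matched dimensions, never against zero.  The near-zero-null property
is asserted in tests at an explicitly moderate bin count (10 bins at
n = 10⁴), where the estimator is dense.

### C3NET and BC3NET

`c3net()` implements the conservative-causal-core rule: each pair gets
a permutation p-value against a pooled null (add-one smoothed), the
pair p-values are BH-corrected, and every node contributes one edge —
to its maximum-MI significant partner (lexicographically first partner
on exact MI ties).  The edge count is therefore bounded by the node
count.  The implementation is checked against an independent
brute-force rule application on random instances in the suite.

`bc3net()` bags C3NET over B = 100 bootstrap resamples of the sample
columns, each resample with its own permutation null (1000 draws by
default).  An edge's support count is tested against
Binomial(B, p0) with p0 = 1/(number of node pairs) — the expected rate
at which a specific pair would be picked by chance — and BH-corrected
at `alpha_ens = 0.05`; surviving edges carry their support fraction as
weight.  The whole procedure is seeded and byte-reproducible.

### MST2, statistics, hubs

MST distances are `d = w_max − w` rather than 1/w, avoiding infinities
as weights approach zero.  Per connected component, MST1 is the
minimum spanning tree of d and MST2 adds the minimum spanning forest
of the component with MST1's edges removed; Kruskal with lexicographic
node-pair tie-breaking makes the reduction deterministic.  MST1
minimality is tested against exhaustive enumeration of spanning trees
(n ≤ 6) and against igraph's MST weight; MST2 always spans its
component with at most 2(n − 1) edges.

`network_stats()` reports: mean degree 2E/N over the giant component;
unconnected taxa as nodes outside the giant component; betweenness as
the unnormalized count of unweighted shortest paths through a node,
endpoints excluded, averaged over giant-component nodes.  The
betweenness convention (weighting, normalization, node set) is a
genuinely open choice in the literature; ours is recorded here and in
the function documentation rather than matched to any particular
published value.

`select_hubs()` computes the degree threshold as the linear-
interpolation percentile (R's quantile type 7) of the degree sequence
over *all* nodes, isolated ones included — the convention under which
the threshold can be a non-integer like 10.10 — and reports as hubs
only nodes with degree strictly above it, so an all-equal degree
sequence has no hubs.

## 4. The synthetic generator

`generate_metaproteome()` emulates the statistical structure the
pipeline assumes: proteins partitioned among taxa (1–20 proteins per
taxon, lengths 80–1500 residues); per-protein baseline means drawn
log-uniformly from 0.5–30 spectra per sample; PT-distributed counts
with dispersion drawn from φ ∈ [1, 10] (the empirical dispersion of
real cecal metaproteomes is not published, so this range is a
recorded, deliberately wide guess); taxon-level planted effects
(default 20% of taxa, |log2FC| ∈ [1, 3], one affected group each — the
analysis unit of the network stage is the taxon, so effects shift all
of a taxon's proteins together); co-abundance modules whose members
share a per-sample log-normal latent factor `exp(ρZ − ρ²/2)` (mean
one, coupling ρ); a fraction (20%) of proteins assigned only at genus
or family rank; and MNAR-light missingness — cells zeroed at
`missing_rate` with below-median-abundance proteins twice as likely,
mimicking the detection limit the downshifted-Gaussian imputation
presumes.  Module members are drawn from the non-DA pool when it is
large enough, so module recovery is not confounded with planted
shifts.  Identical config and seed give byte-identical TSV/JSON
output.

What it does **not** emulate: peptide-to-protein inference and shared
peptides, identification FDR, protein-length/abundance correlation,
taxonomic misassignment, compositional closure of the instrument
(total spectra per run are not fixed), or realistic phylogenetic
correlation between taxa.  Passing the suite therefore demonstrates
that the inference chain recovers the structure it models — not that
any particular biological claim about real cecal samples is
reproduced.

## 5. Problem sizes and numerical conventions

The test and acceptance workloads are sized to run comfortably on a
laptop: type-I calibration uses 2000 null replicates; power uses 100
taxa × 20 seeds (planted 4-fold effects, μ = 50, φ = 2, n = 4/group);
module recovery uses 30 taxa, three 5-taxon modules at ρ = 0.9, B =
100 bootstraps × 20 seeds; oracle equivalence uses 100 random
instances each for C3NET (≤ 5 nodes) and MSTs (≤ 6 nodes).

Conventions for degenerate inputs are uniform across the package:
empty results are legal (an empty filter result or an empty
significant-edge set warns, never errors); constant vectors give MI 0
with a warning; all computations that consume randomness take an
explicit seed and restore the caller's RNG state.  Determinism is
asserted at the byte level for the generator and the full pipeline
(md5 manifest).

## 6. Known limitations

* The PT fit is moment-based with a three-point shape grid; no
  maximum-likelihood fit over continuous a, and no shrinkage of
  dispersions across taxa (an empirical-Bayes layer would help at
  n = 4).
* The DA test's Poisson-null conservatism (see §2) trades power for
  safety on equidispersed taxa.
* MI at 16 samples is heavily binned; the permutation null absorbs
  the bias but fine dependence structure is not resolvable at this n.
* Enrichment treats annotation terms as flat sets; no ontology-graph
  propagation.
* The network is undirected and unsigned; co-exclusion (negative
  dependence) is detected by MI but not distinguished from positive
  dependence in the edge list.
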