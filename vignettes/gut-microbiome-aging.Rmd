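---
title: "Methods: from gene profiles to microbe-metabolite-age linkages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from gene profiles to microbe-metabolite-age linkages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutage)
```

gutage implements the computational core of a multi-omics analysis linking
the gut metagenome, the serum metabolome, and aging: co-abundance clustering
of gene profiles into metagenomic species (MGSs), rule-based taxonomy,
community ecology statistics, random-forest models of metabolites, and a
bidirectional mediation screen that asks whether a microbe's association
with age runs through a serum metabolite. This vignette explains each
procedure, its assumptions, and the design choices that were genuinely open.

## Data model

Abundance tables are wide tibbles: a `feature_id` column plus one numeric
column per sample. Relative-abundance tables are compositional — every
sample column sums to 1 — which matters twice below: Bray-Curtis distances
assume it, and compositional closure induces small negative correlations
between unrelated taxa that the canopy thresholds must (and do) tolerate.

## Canopy clustering into CAGs and MGSs

Genes from the same genome rise and fall together across samples, so
clusters of co-abundant genes act as proxies for species. `build_canopies()`
picks seed genes in descending order of total abundance (ties broken by gene
id) and captures every unclustered gene whose profile correlates with the
canopy profile at Pearson > 0.9 *and* Spearman > 0.6; the canopy median
profile is then recomputed and membership recaptured once (`recenter_iters`,
default 1). Captured genes leave the pool, so canopies never overlap.
Canopies whose median profiles correlate at Pearson >= 0.97 are merged
transitively (union-find, hence order-independent). Filters then discard
canopies with <= 2 genes, canopies whose top three samples hold >= 90% of the
summed member-gene signal, canopies detected in fewer than 4 samples, and
canopies with one sample holding >= 90% of the signal. Survivors are CAGs;
CAGs with more than 700 genes (strictly) are MGSs, and their per-sample
abundance is the median of their member genes (midpoint convention for even
sizes).

Open choices, and how they were fixed:

* *Seed order.* Unstated in the method's description; descending total
  abundance is used because abundant genes have the best-estimated
  correlations, and it makes the algorithm fully deterministic.
* *Exclusive assignment.* Seeds are drawn from "not yet clustered" genes,
  which implies non-overlapping canopies; recapture is therefore restricted
  to the unclustered pool plus current members.
* *Merge rule.* "Within a distance of 0.97 Pearson" is read as correlation
  >= 0.97; a distance reading (1 - r <= 0.97) would merge nearly everything
  and defeat the method's purpose. Transitive closure is used because no
  merge order is specified and closure is the only order-independent choice.
* *Degenerate profiles.* Zero-variance genes have undefined correlations;
  they cannot seed or be captured and end as singletons, which the size
  filter then removes.

Scalability: correlations against a seed are computed with one centered
matrix product over the full gene set, so desk-scale catalogs (10^4-10^5
genes, 10^2 samples) cluster in seconds. The validation suite runs the
full pipeline at 150 samples x 6,000 genes (30 planted species of 200
genes); adjusted Rand index against the planted species exceeds 0.9 there
(and in practice is ~1.0).

## Rule-based taxonomy

Gene-level: alignments under 70% query coverage are dropped; the best hit is
the maximal bit score. When tied best hits span several species, the species
with the highest frequency among the tied hits wins, then highest mean
identity, then lexicographic order (a documented, deterministic precedence:
bit score, frequency, mean identity, name). Rank follows best-hit identity
with inclusive thresholds: >= 95% species, >= 85% genus, >= 65% phylum, else
unassigned.

MGS-level: a species call requires >= 90% of member genes hitting one
species at >= 95% identity and >= 70% coverage; otherwise a genus call
requires >= 80% of genes at >= 85% identity; otherwise unclassified.
Fractions are computed over *all* member genes, annotated or not, which is
the conservative reading. The hit tables carry a single (DNA) identity
field; the protein-identity side condition of the genus rule is a documented
simplification.

## Ecology

* `shannon()`: `H' = -sum(a_i ln a_i)` in nats, renormalized internally.
* `bray_curtis()`: `sum|x-y| / sum(x+y)` via vegan; bounded in [0, 1], not a
  metric (triangle inequality may fail — asserted nowhere, by design).
* `intragroup_beta()`: within-group pairwise distances compared across
  groups by Wilcoxon rank-sum. Pairwise distances are dependent, so these
  p-values are screening devices, not calibrated tests.
* `enterotype()`: distance = sqrt of Jensen-Shannon divergence between genus
  profiles (zeros replaced by a 1e-9 pseudocount), medoid clustering
  (`cluster::pam`) for each candidate k, and k chosen by the
  Calinski-Harabasz index computed directly from the distance matrix
  (between/within sums of squares from pairwise distances). All three
  components are the classic enterotyping choices; each is replaceable via
  arguments because the procedure is a convention, not a theorem.

## PERMANOVA effect sizes

`permanova_r2()` is authored in-package because the validation contract
needs an exhaustive-permutation mode with exactly reproducible p-values.
Squared distances are Gower-centered, `G = -1/2 J D^2 J`; with the
idempotent hat matrix `H` of the covariate design, `SS_model = tr(HG)`,
`R^2 = SS_model / tr(G)`, and the pseudo-F compares model to residual mean
squares. Permutation p-values use the add-one convention
`(1 + #{F_perm >= F_obs}) / (1 + n_perm)` so p is never zero; with
`exact = TRUE` all n! permutations are enumerated and the identity
permutation keeps p positive. Ties against the observed F are counted with
a 1e-12 guard so that algebraically identical permutations are not split by
rounding. vegan's `adonis2` serves as an independent cross-check in the
test suite, never as the implementation.

`effect_size_decomposition()` mirrors the three-step procedure used for
serum-metabolome variance: (1) single-covariate R^2 with permutation p,
keep p < 0.05; (2) redundancy pass in descending R^2 dropping any covariate
correlated > 0.5 (|Pearson|) with an already-retained one — which member of
a redundant pair survives was unspecified, and keeping the higher-R^2 one
is the deterministic choice that preserves explanatory power; (3) combined
effect size = total model R^2 of the sequential fit of retained covariates.
Because retained covariates may overlap, the combined R^2 is at least the
best single R^2 but less than the sum.

## Clinical formulas

`egfr_ckd_epi()` implements the four-branch CKD-EPI creatinine equation
(female knot 0.7 mg/dL, male 0.9; age factor 0.993^age; no race
coefficient), continuous at the knots, strictly decreasing in age and
creatinine. The male low-creatinine exponent is -0.411 by default (the
published CKD-EPI value); -0.4111, a variant seen in print, is available
via `male_low_exponent`. `telomere_ts()` computes T/S = 2^-ddCt with
arithmetic averaging of replicate Ct values (the standard ddCt practice;
the aggregation rule is not otherwise specified) and is invariant to
constant Ct shifts.

## Random-forest forward selection with Q2

For a metabolite response and MGS predictors, the first variable is the one
with the largest permutation importance (%IncMSE) in a forest on all
candidates; each subsequent step adds the candidate whose inclusion
maximizes leave-one-out Q^2, stopping when the best addition improves Q^2
by <= 1e-6 (ties count as "no increase"). Q^2 is `1 - RSS/TSS` on held-out
predictions; the final Q^2 x 100 is the "variance explained" reported for a
metabolite. Forests use 500 trees and regression mtry = floor(p/3)
(configurable); LOOCV folds are seeded as `seed + fold`, making the whole
procedure bit-reproducible. An alternative first-step rule (best
single-variable Q^2) is available via `first = "q2"`.

`correlation_power()` gives the power of the two-sided test of rho = 0 via
the Fisher z approximation; at r = 0 it returns alpha, the size of the
test, exactly.

## Bidirectional mediation

`mediate_interaction()` fits `m ~ x` and `y ~ x + m + x:m` by least squares
and estimates effects by quasi-Bayesian simulation: 1,000 parameter draws
from the asymptotic normal distributions, closed-form potential-outcome
contrasts per draw (valid because both models are linear), ACME and ADE
averaged over the two treatment arms so ACME + ADE = total exactly.
Percentile intervals and two-sided simulation p-values come from the draws.
Because a 0/1 contrast is meaningless for relative abundances, the default
contrast is mean(x) to mean(x) + sd(x); treat/control values are
configurable. "Inverse mediation" swaps mediator and outcome: the forward
run is microbe -> metabolite -> age, the inverse run microbe -> age ->
metabolite, and a linkage passes the screen iff p_forward < 0.05 and
p_inverse > 0.05, after a Spearman prefilter (p < 0.05 by default; a BH
q-value mode is provided because the original feature-level FDR prefilter
is ambiguous between per-pair and per-feature). Age enters as a continuous
outcome; no covariates are adjusted inside the mediation models.

**When can the filter actually tell direction?** In a linear-Gaussian
chain the mediator-outcome partial association given the exposure is
direction-symmetric: the t-statistic of m in `y ~ x + m` equals the
t-statistic of y in `m ~ x + y` (both ~ b·sigma_m·sqrt(n)). The two ACME
p-values therefore differ only through each run's weaker product factor —
the exposure-mediator path forward, the exposure's *total* association with
the outcome inverse. The filter separates direction only when both path
associations are individually strong (z >= ~4) while the total
exposure-outcome association is weak (z <= ~0.3), which forces
`n >~ (z_path^2 / z_total)^2`. The directional validation therefore runs at
n = 8,000 with a = b = 0.05 and unit noise — the weak-effect, large-cohort
regime typical of single-taxon aging signals — where planted forward chains
pass and planted reverse chains fail in >= 90% of replicates. At strong
effect sizes (a = b = 0.5, n = 200) *both* directions are significant and
the filter rejects everything; this is a property of the method, not of the
implementation, and is the main caveat for interpreting screen hits on real
cohorts.

## The synthetic cohort generator

`generate_cohort()` produces the structure every downstream stage assumes,
with recorded ground truth:

* ages uniform on 20-111 years (a grouping helper bins at 60/90/100 to
  mirror four-group cohort designs); sex Bernoulli(0.5); serum creatinine
  `0.6 + 0.004·age + N(0, 0.1)` floored at 0.3 mg/dL — invented, but it
  places subjects on both sides of both CKD-EPI knots;
* species log-abundances `mu_s + slope_s·(age - midpoint) + N(0, 1.5)`,
  exponentiated and closed to 1 per sample. The 1.5 log-unit spread is the
  realistic heavy-tailed regime (species ranging over orders of magnitude);
  it also determines how sharp within-species gene correlations are.
  Default age slopes are ±0.02 per year on five species;
* gene abundances = species abundance x fixed per-gene log-normal
  multiplier x multiplicative noise (log-SD 0.2 default), then
  detection-limit dropout — per gene, the lowest `dropout_prob` quantile of
  its values is zeroed — then per-sample renormalization. Dropout is a
  detection limit rather than uniform random erasure deliberately: uniform
  10% erasure caps within-species Pearson near 0.86, below the canopy
  capture threshold, and no clustering method could then recover the
  planted species; detection-limit zeros co-occur across a species' genes,
  as they do in real profiles;
* metabolites = baseline + 50 x producer-species relative abundance +
  N(0, 0.5) for the first third of metabolites; the rest are noise;
* mediation chains: age is drawn first, then the chain's (x, m) pair is
  drawn from the conditional Gaussian of the chain model `x -> m -> y`
  given the standardized age. This plants the chain's full second-moment
  structure — which is all linear mediation models see — without disturbing
  the uniform age design. The default chain (a = b = 0.5, c' = 0,
  noise_m = 0.3, noise_y = 1) is a strong, clearly detectable effect used
  for recovery checks; directionality validation uses the weak-effect
  regime described above;
* alignment hit tables (best hit to the true species at ~97% identity,
  optional decoys and injectable bit-score ties, fabricated deterministic
  lineage) and telomere qPCR plates (3 replicates per target, per-plate
  standard) complete the inputs.

Identical configurations and seeds give bit-identical cohorts. What the
generator does *not* emulate: read-level sampling noise, assembly
artifacts, realistic phylogeny, non-linear microbe-metabolite relations,
and metabolite-metabolite correlation structure. Passing tests therefore
demonstrate correctness of the procedures under the generative assumptions,
not robustness to everything real data does.

## Problem sizes and numerical conventions

The validation suite runs canopy recovery at 150 samples x 6,000 genes;
PERMANOVA null calibration over 200 simulations of 20 samples with 999
permutations each, plus exhaustive-permutation equivalence at n = 6 and 7;
mediation calibration at n = 500 with null screens over 200 replicates of
n = 200 and directional screens over 200 replicates of n = 8,000; and
forest selection over 50 seeds at n = 60 with 10 candidates. These sizes
were chosen so the full suite runs in minutes on one core while leaving
each statistical check comfortable margins.

Conventions worth knowing: permutation p-values are never zero (add-one
convention, or enumeration including the identity); BH q-values come from
`stats::p.adjust`; Spearman p-values are exact for n < 10 without ties and
t-approximate otherwise; partial Spearman with an exactly collinear
covariate returns rho = 0 rather than failing, because the conditional
variance is zero; all forests, folds, permutations and simulations derive
their seeds from user-supplied integers.
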