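---
title: "Models and methods in coanpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in coanpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

coanpipe implements a haplotype-sharing analysis pipeline for phased SNP
panels: chromosome painting, coancestry-based clustering, a bootstrap test
for admixture-driven coancestry inversions, sum-to-one ancestry profiles,
spatial smoothing, and admixture dating from ancestry-covariance decay.
This vignette records the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic-data generator does
and does not emulate.

## The copying model and expected-length painting

A recipient haplotype is modelled as an imperfect mosaic of the `D` donor
haplotypes (the Li-and-Stephens hidden Markov model). The hidden copying
state switches along the genetic map as a Poisson process: between adjacent
SNPs separated by `d` cM the state is retained with probability
`exp(-rho d)` and otherwise redrawn uniformly over donors. The observed
allele matches the copied donor's allele with probability `1 - theta`.

Two parameters, both plain configuration (`copying_params()`), control the
model:

* `switch_rate` (`rho`, per cM; default 0.1): the expected chunk scale is
  `1/rho` cM. The reference painting software estimates an analogous rate by
  EM; here it is fixed and logged, because the downstream contracts (row-sum
  conservation, oracle equivalence, cluster recovery) do not require the
  estimation step, and a fixed rate keeps every stage reproducible.
* `miscopy` (`theta`, default 0.01): tolerance for mutation and genotyping
  error.

Expected copied length per donor is computed by forward–backward; each
inter-SNP interval is attributed according to the posterior at its **left**
SNP, a deliberate, simple convention that makes the per-haplotype totals sum
*exactly* to the map length and is checkable against brute-force path
enumeration (the reference implementation's exact interval expectation
differs slightly; equivalence is not claimed). An expected chunk-*count*
measure is available behind `measure = "count"`; on structured panels it
ranks donors the same way as chunk length (Spearman rho > 0.9 in the test
suite), but chunk length is the default measure as it is the more robust
choice on real data.

Diploid handling: each recipient haplotype is painted separately with the
individual's own two haplotypes left out; donor individuals' two haplotypes
are pooled. The square coancestry matrix therefore has zero diagonal and
rows summing to twice the map length.

## The clustering model

Clustering works on effective counts: the coancestry matrix is divided by a
c-factor and rounded (half-to-even, with the row total repaired on the
largest entry so rounding never changes row sums). The c-factor converts cM
into effectively independent segments; its data-driven default is the mean
chunk length computed from the same painting (total expected length / total
expected chunks). A published analysis of this kind used an externally
derived value (0.0579 in the restricted analysis we mirror); any positive
value can be supplied.

Given a partition, each individual's count row is multinomial over donor
*columns* with probabilities equal within a donor cluster
(`q_{a,b} / n_b`, with the row's own zero column excluded, so `n_b - 1`
available columns inside its own cluster), and the cluster-level
probability vectors `q_a` are integrated out under a symmetric
Dirichlet(`beta = 1`). A CRP(1) prior completes the posterior over
partitions; the number of clusters is inferred, never fixed. The MCMC uses
Gibbs single-individual reassignment (including opening a new cluster) plus
a split/merge Metropolis-Hastings move, all seeded; ties break on the
smallest index. On exactly block-structured matrices the MAP equals the
blocks — verified exhaustively over all 4140 partitions of 8 individuals in
the tests.

The greedy tree merges the pair of clusters whose merge least decreases the
posterior, with lexicographic tie-breaking; scores are clamped at zero.
Assignment certainty for individual `i` and final cluster `k` averages,
over MCMC samples, the overlap `|(c_s(i) \ {i}) ∩ k| / |c_s(i) \ {i}|`.
Excluding the individual itself makes the certainty of an individual whose
sampled co-members are exactly cluster B equal 1 for B (and 0.5/0.5 when
samples alternate between two clusters), and rows still sum to one. A
sampled singleton credits its final cluster.

**External-sharing clustering.** To cluster recipients only on what they
copy from external donor groups, the rectangular matrix X is embedded as
C = [0 X; 0 Y]. Y is zero except within-donor-group diagonal blocks whose
entries all equal `g_k`, the mean of group k's entries of X — so the group
mean in Y equals that in X to machine precision regardless of whether the
diagonal self-pairs are conceptually included (an ambiguity in the source
method description; we include them, which the block-mean calibration makes
immaterial). The zero blocks remove recipient-recipient sharing from the
likelihood; donor groups are forced (never split or merged). Private drift
within a recipient deme then cannot create clusters: a strongly drifted
deme with the same external sharing as its neighbour merges with it, while
a deme with 20% external admixture separates.

## The drift/admixture bootstrap test

For every ordered cluster pair, 200 resamples draw an equal-size subsample
(13 by default, without replacement — coancestry is undefined for an
individual with itself) from each cluster with at least that many members;
the coancestry matrix is *repainted* on the subsample (not sliced from the
full matrix, since painting is relative to the sample); the mean
within-recipient coancestry (diagonal excluded) is compared with the mean
recipient-source coancestry. `S` counts the null-consistent resamples
(within >= cross) and `p = (S + 1)/(n + 1)`, so a consistent excess of
cross-coancestry gives a small p; pairs with `p < 0.02` are flagged,
uncorrected for multiplicity. The source text's literal sentence defines S
with the opposite inequality, which would make excess-cross pairs score
p near 1, contradicting the accompanying figure's significance convention;
the direction implemented here is the one consistent with that figure.

The two-focal-cluster demonstration scenarios embed the alpha/beta pair in
three mildly drifted background demes. This is not cosmetic: with only two
clusters in the sample, beta's background copying has nowhere to go but
beta, so the within/cross inversion is arithmetically impossible at
moderate admixture fractions; with backgrounds absorbing the spread (as the
many other clusters do in a real cohort), a pulse of 0.4 from a strongly
drifted alpha flips the ordering robustly, while a pure split or admixture
into alpha leaves it intact.

## Ancestry profiles

The donor basis B has one row per donor group: each donor individual is
painted against all donor haplotypes except its own two (by default its own
group's other members are allowed — keeping B square; a flag excludes the
whole group), results are group-averaged and normalized to proportions.
A target vector (cluster-averaged, donor-self, or per-grid-cell) is fitted
as `min || B' beta - y ||` subject to `beta >= 0, sum(beta) = 1`. The
solver is Lawson-Hanson active-set NNLS with the sum-to-one constraint as a
heavily weighted augmentation row (no constrained-LS solver ships with the
supported stack, so the primitive is implemented in the package and checked
against an exhaustive simplex grid search at step 0.01). Coefficients below
1e-4 are zeroed and the profile renormalized — a display convention for
trace components. Uncertainty comes from the pseudo-individual bootstrap:
each pseudo-individual takes a random cluster member per chromosome and
sums chromosome-level vectors; a cluster-size set of pseudo-individuals is
averaged and refitted, 1000 times, reporting the inner 95%. A group is
`reported` when its interval excludes zero and the point estimate exceeds
0.001.

## Spatial smoothing

Individuals are placed at the centroid of their four grandparental
coordinates and retained when all four lie within 80 km of the centroid
(the alternative "within 80 km of each other" reading is available as
`rule = "pairwise"`; the two appear interchangeably in the source
descriptions). Coinciding display points are jittered uniformly in a disk
of radius <= 24 km, seeded. Coordinates are planar km throughout — the
smoothing mathematics only needs a metric, and the maps this emulates are
national-scale.

Cluster maps colour a regular 3-km grid by normalized Gaussian kernel
densities of each cluster's members. Smoothed copying fields use an
adaptive bandwidth: at each cell, the kernel sd is
`max(base_bw_km, distance to the k-th nearest retained individual)`
(defaults k = 10, base 3 km) — a stand-in for the published
density-adaptive rule, whose exact form is not in the available text. Cells
in a designated no-fine-geography region (the analogue of a neighbouring
country with only country-level locations) all receive the plain average
vector of the designated individuals. Cells with numerically zero total
weight are flagged, never silently zeroed.

## Admixture dating

Per-SNP copying posteriors over donor groups (`paint_posteriors()`) are the
raw material. For each pair of donor groups and each genetic-distance bin
(1-cM bins spanning 1–50 cM by default), the curve value is the mean
product of posteriors at within-chromosome position pairs in the bin,
after **centring per position across haplotypes**. Centring matters:
locally informative SNP context shifts all haplotypes' posteriors together,
and without it those shared position effects masquerade as slowly decaying
ancestry covariance (we observed spurious "dates" of 2–5 generations and
false admixture evidence before centring).

After a single pulse g generations ago the curves decay as
`exp(-g d / 100)` (d in cM). Dating fits all pair curves jointly with one
shared decay rate: the rate is profiled on a deterministic grid (1..60 per
Morgan), the per-curve amplitudes and intercepts solved linearly, then the
rate polished by bounded local optimization — noiseless curves are
recovered to ~1e-9. For dating we paint with `switch_rate = 2` per cM so
the copying chunk scale (0.5 cM) sits well below the 3-cM short-range
cutoff used in the analyses (the package default cutoff is 1 cM; within-
chunk autocorrelation decays at `rho` per cM, so the cutoff should be a few
chunk lengths — with the default painting rate of 0.1 the first bins are
dominated by chunk structure and a larger cutoff or faster rate is needed).

Evidence for admixture is a permutation test: each haplotype's posteriors
are shuffled within chromosomes (destroying all distance structure while
keeping composition), the shared-rate fit is recomputed, and the statistic
compared is the amplitude norm **evaluated at the shortest fitted
distance** — extrapolating to d = 0 would let the null chase high-rate
noise. p = rank of the observed statistic among `n_null = 100` replicates;
the smallest achievable p is 1/101, so detection at p < 0.01 requires
beating every replicate. The permutation comparison runs on 2-fold-thinned
SNPs (applied identically to observed and null statistics) purely for
speed.

Proportions and sources: the fitted amplitude matrix is, in expectation,
`alpha (1 - alpha) delta delta'` with `delta` the difference between the
two sources' painted copying profiles. Its leading eigenvector gives the
direction of `delta`; for each candidate minor fraction alpha on a grid
(0.02–0.5) the implied source profiles `mu + (1 - alpha) delta` and
`mu - alpha delta` are projected onto the donor basis by simplex NNLS. The
residual is flat above the feasibility boundary (larger alpha shrinks
delta and keeps both profiles inside the basis hull), so the reported
alpha is the *smallest* grid value within a factor of two of the minimum
residual — the most-distinct-minor-source convention. Ties at 0.5 report
0.5. Calendar conversion is `year = 1940 - 28 g` (28-year generations,
current generation dated 1940), exactly and invertibly.

One- versus two-date comparison fits one and two exponentials per curve;
the RSS-reduction statistic is calibrated by a parametric bootstrap under
the one-date fit (Gaussian residuals), a separate decay-versus-constant
bootstrap labels no-signal curves `"no-decay"`, and the overall verdict is
"two-date" only when a curve involving a designated group (default: any)
prefers two dates — mirroring the qualitative published rule, made
explicit as configuration.

Date uncertainty resamples target individuals with replacement, reusing
cached per-individual bin sums (position centring is held fixed from the
full sample — a deliberate approximation that keeps 1000-fold bootstraps
cheap), and reports the inner 95% of refitted dates.

## The generator's stated world

`demographic_scenario()` draws per-pool allele frequencies by
Balding-Nichols perturbation of a shared uniform(0.05, 0.95) base pool
(`F` = the deme's drift), then samples haplotypes i.i.d. given frequencies.
Admixture pulses lay tract boundaries as a Poisson process at `g` per
Morgan and label each inter-boundary segment source with probability
`alpha`, independently; segments are recorded unmerged, so segment lengths
are exactly Exp(mean 100/g cM), which is what the dating theory uses.
Source material for admixed tracts is drawn *fresh* from the source pool's
frequencies (falling back to copying sampled haplotypes when frequencies
are unavailable): the historical admixers were distinct members of the
source population, and exact copies of panel donors would make admixed
tracts paint with unrealistically perfect confidence, biasing the inferred
mixing proportion upward (we measured alpha-hat 0.29 for a true 0.1 with
exact copies, 0.10–0.13 with fresh draws).

What a green test does and does not establish: the generator has no linkage
disequilibrium within pools, no mutation or genotyping error, uniform maps
by default, planar geography, and single-generation pulses. Tests passing
here validate the algorithms' contracts (conservation, oracle equivalence,
parameter recovery, calibration under the model), not performance on real
cohorts with background LD, phasing error and continuous admixture.

Default scales were chosen once, as the smallest worlds in which the
published effects are resolvable: 3 demes x 20 diploids at drift ~0.2 on
2 x 100 cM x 800 SNPs for cluster recovery; 5 x 150-160 cM genomes with a
strongly diverged source pool (F = 0.5) for external-sharing clustering and
dating; 18 diploids per deme (so 13-of-18 subsampling varies) for the
bootstrap drift test. Individual-level assignment in the external-sharing
analysis is the most marginal contract at these scales: one borderline
individual in ~4 seeds crosses clusters, which is the honest behaviour of
the likelihood on data of this size.

## Known limitations

* The clustering likelihood is a Dirichlet-multinomial product-partition
  stand-in for the reference software's full model; no numerical parity is
  claimed, and hyper-priors (`beta`, CRP concentration) are fixed, not
  estimated.
* Painting parameters are not EM-estimated; badly mis-set rates degrade
  (but do not bias the direction of) downstream contrasts.
* The dating module is a declared simplification of the full
  admixture-dating software: no surrogate re-painting, no null-individual
  standardization, two-way single-pulse events only; its contract is
  parameter recovery under the generator's model.
* The permutation evidence test controls the no-distance-structure null;
  extremely strong residual chunk autocorrelation (slow painting rates with
  a 1-cM cutoff) can still inflate evidence, which is why dating paints at
  `switch_rate = 2`.
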