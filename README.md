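# coanpipe

Haplotype-based analysis of fine-scale population structure and admixture
history, for population geneticists working with phased SNP panels. The
package implements, end to end and on fully synthetic data if desired, the
haplotype-sharing toolkit used in fine-scale studies of national cohorts:

- **Chromosome painting.** Each individual's haplotypes are modelled as a
  mosaic of the other sampled haplotypes under a Li-and-Stephens copying
  model. The forward–backward algorithm yields, for each donor, the expected
  genome length (in cM) copied from it — the *coancestry* of the pair. Row
  sums are conserved (2 × map length per diploid), and a chunk-count measure
  is available alongside the default chunk-length measure.
- **Coancestry clustering.** A Dirichlet-multinomial partition model on the
  1/c-scaled, rounded coancestry matrix (the fineSTRUCTURE model family),
  sampled by MCMC with Gibbs and split/merge moves; the number of clusters is
  inferred. Greedy merging builds a cluster tree; per-individual assignment
  certainties come from the MCMC trace.
- **Clustering on external sharing.** The rectangular matrix X of copying
  from external donor groups is embedded in a calibrated block matrix
  C = [0 X; 0 Y] (Y carrying per-group constants g_k with mean matched to X),
  with donor groups forced, so recipients cluster purely on their sharing
  with outside groups; structure due to private drift disappears.
- **Drift/admixture bootstrap test.** For each cluster pair, equal-size
  subsamples are repainted and mean within-cluster coancestry is compared
  with cross-cluster coancestry; p = (S + 1)/(n + 1) over resamples. An
  excess of cross-coancestry is the signature of admixture from a strongly
  drifted relative of the source cluster.
- **Ancestry profiles.** Each cluster's donor-group copying vector is
  expressed as the best non-negative, sum-to-one mixture of donor-group
  self-copying vectors, with pseudo-individual (per-chromosome) bootstrap
  intervals.
- **Spatial smoothing.** Individuals placed at grandparental-birthplace
  centroids (80-km retention filter, ≤24-km display jitter), cluster density
  maps, and adaptive-bandwidth Gaussian smoothing of copying vectors on a
  3-km grid, with per-cell ancestry profiles.
- **Admixture dating.** Coancestry curves — the covariance of copying
  ancestry between genome positions as a function of genetic distance — decay
  as exp(−g d/100) after a pulse g generations ago. A shared-rate exponential
  fit across donor-group pairs dates the event; a rank-one decomposition of
  the amplitude matrix recovers the mixing proportion and the two source
  compositions; calendar years use year = 1940 − 28 g.
- **Synthetic panels.** Balding-Nichols drifted demes with geography,
  external donor pools, and dated Markov ancestry-tract pulses (segment
  lengths exponential with mean 100/g cM), with full truth records, so every
  stage can be validated against known parameters.

## Worked example

```r
library(coanpipe)

# a stated world: three drifted demes, two external pools, one dated pulse
scenario <- default_scenario(seed = 1)
sim <- simulate_structured_panel(scenario)
demes  <- panel_subset(sim$panel, sim$panel$samples$id[sim$panel$samples$role == "deme"])
donors <- panel_subset(sim$panel, sim$panel$samples$id[sim$panel$samples$role == "donor"])

cmx <- coancestry_square(demes)
fit <- fs_mcmc(cmx, seed = 3)
fit
#> <fs_fit> 60 individuals in 3 clusters (MAP log-posterior -51350.656, 150 retained samples)
adjusted_rand_index(fit$partition$cluster,
                    as.integer(factor(demes$samples$group)))
#> [1] 1

# date the simulated pulse (alpha = 0.1, g = 30) from coancestry curves
pars <- copying_params(switch_rate = 2)
B  <- donor_basis_vectors(donors, pars)
pp <- paint_posteriors(panel_subset(demes, demes$samples$id[demes$samples$group == "C"]),
                       donors, pars)
ev <- infer_two_way_event(pp, B, min_cm = 3, n_null = 100, seed = 2)
ev
#> <admixture_event> g = 37.81 generations ( 881.192 CE ), minor proportion = 0.13
```

The clustering ARI of 1 says the three demes are recovered exactly; the
event summary says a two-way admixture pulse is detected (p < 0.01 against
the permutation null), dated to ~38 generations before 1940 with minor-side
proportion 0.13 — bracketing the simulated g = 30, alpha = 0.1 on the
deliberately small default panel (the two-chromosome default genome dates
far less precisely than the five-chromosome world used in the test suite,
where median date error is under 10%).

Each result type has tidyverse hooks: `tidy()`/`glance()` for fits and
events, `autoplot()`/`plot_*()` for matrices, curves, profiles and maps, and
every table is a tibble.

## Pipeline and acceptance script

`run_pipeline(pipeline_config(seed = 1), "out/")` executes
simulate → paint → cluster → test-drift → profile → smooth → date and writes
every artifact as TSV/Newick/JSON under `out/`; reruns with the same config
are byte-identical.

`scripts/acceptance.R` re-runs that end-to-end computation from scratch on
the default scenario under a given seed and writes the acceptance report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
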