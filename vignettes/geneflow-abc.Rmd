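---
title: "Inferring three-population gene flow by coalescent simulation and ABC"
author: "coalABC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring three-population gene flow by coalescent simulation and ABC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The inference problem

coalABC addresses a recurring question in phylogeography: when three closely
related populations show shallow genetic differentiation, is that the
signature of ongoing or episodic gene flow, or merely of recently shared
ancestral polymorphism? The package is built around the Andean
flycatcher system that motivates its defaults — three taxa here labelled
*chilensis* (C), *pallatangae* (P) and *albiceps* (A) — but every component
is parameterised and applies to any three-population system with a known
((C, P), A) topology, multilocus Sanger-scale sequence data, and no
within-locus recombination.

The approach is likelihood-free. A structured-coalescent simulator draws
multilocus datasets under competing demographic models; each simulated
dataset is reduced to a vector of summary statistics; and Approximate
Bayesian Computation (ABC) compares those vectors with the observed one to
(i) choose among models and (ii) estimate the favoured model's parameters.

## The demographic models

All models share a fixed three-deme topology: P merges (backward in time)
into C at `T_CP`, and the C+P ancestor merges into A's lineage at `T_A`,
with `T_CP < T_A` enforced on every prior draw. Deme sizes are constant.
Seven models differ only in their migration structure between *terminal*
demes:

| Code | Gene flow |
|------|-----------|
| A | none |
| B | C–P only |
| C | C–A only |
| D | C–P and C–A, one shared rate |
| E | all three pairs |
| F | C–P and C–A, independent rates with `m_CP > m_CA` |
| G | as F, but no gene flow at backward times below `tIso` |

Model G is the isolation-with-migration scenario of interest: montane
habitat bands shift downslope during glacial periods and connect adjacent
ridges, so gene flow is possible during glacials but not during the current
interglacial. `tIso` defaults to 20,000 generations — the package
identifies "roughly 20 kya" with 20,000 generations at a one-year
generation time; the knob is exposed in `getModel()` for other generation
times.

"Symmetric" gene flow means a single rate per pair applied in both
backward directions; rates are backward per-lineage per-generation
migration probabilities. Two conventions had to be fixed where a
three-size parameterisation leaves them open, and both are package design
choices:

* **Ancestral deme sizes.** The models have exactly three size parameters
  (`N_C`, `N_P`, `N_A`). After each merge the surviving deme keeps its own
  size: the C+P ancestor has size `N_C`, the root has size `N_A`. This is
  the minimal convention consistent with constant sizes and no extra
  parameters.
* **No ancestor–A migration.** Between `T_CP` and `T_A` the C+P ancestor
  exchanges no migrants with A: migration edges connect terminal demes
  only, so every edge is inactive from `T_CP` backwards.

Model F and G's rate asymmetry is enforced as an ordering constraint
(`m_CP > m_CA`, violating draws redrawn); an independent-priors mode
without the ordering is available via `drawParameters(orderedRates =
FALSE)`, since either reading is defensible.

## Priors

All priors are uniform: deme sizes 10–100,000 individuals, `T_CP`
10,000–2,000,000 generations, `T_A` 1,000,000–7,000,000 generations, and
migration probabilities 1e-8–1e-4 per lineage per generation. For
mitochondrial analyses the size bound drops to 25,000 (one quarter of the
autosomal bound, reflecting the four-fold smaller effective size of a
maternally inherited haploid marker) and each sampled individual
contributes a single gene copy; a deme of `N` individuals holds `2N`
autosomal but `N` mitochondrial copies in the simulator.

## The simulator

`src/coalescent.cpp` implements the standard event-driven
continuous-time structured coalescent: within-deme coalescence of `k`
lineages at rate `k(k-1)/2` divided by the deme size in gene copies,
competing with per-lineage migration at the active backward rates, with
deterministic lineage movements at `tIso`, `T_CP` and `T_A`. This is the
usual continuous-time approximation of the Wright–Fisher model, accurate
for the population sizes in the priors; no per-generation simulation is
performed. All randomness flows through R's RNG, so a single `set.seed()`
makes every simulation — including 50,000-row reference tables —
bit-reproducible.

Mutations follow an infinite-sites model per locus: the mutation count is
Poisson with mean (total branch length × per-site rate × locus length),
each mutation falls on a branch chosen proportionally to length and
occupies its own site. All default statistics depend only on
segregating-site patterns, for which infinite sites is cheap and unbiased
at shallow divergences. When a draw demands more mutations than the locus
has sites — which happens for deep-divergence prior draws at elevated
mutation rates — a finite-sites fallback reuses positions with allele
toggling, reproducing saturation, and the table builder emits one summary
warning counting affected locus simulations.

Per-locus mutation rates are deliberately explicit everywhere. Defaults
are order-of-magnitude avian conventions, 1e-9 per site per generation for
nuclear loci and 1e-8 for the mitochondrial gene; every
`SimulationRequest` carries its rates, and analyses that depend on them
state them.

## Summary statistics

The default 13-component vector (`statNames()`) contains, for the three
focal populations: per-population segregating sites `S_p` and mean
pairwise differences `pi_p` (per locus, not per site), pooled segregating
sites, pairwise between-population mean differences `d_pq`, and pairwise
Hudson FST (`1 - piw/pib`). The set follows what the statistics must
capture — within-population variability, between-population
differentiation, and shared variation — and is identical, in definition
and order, for observed and simulated data.

Conventions shared by every statistic:

* Only unambiguous bases (A, C, G, T) enter a comparison. IUPAC ambiguity
  codes — used for unphased heterozygous sites — and missing symbols
  (`N`, `-`, `?`) are excluded site-wise ("pairwise deletion"), never
  half-counted, which avoids phasing assumptions.
* Aggregation across loci is the arithmetic mean per statistic, except
  FST, which is the ratio of across-locus means
  (`1 - mean(piw)/mean(pib)`): the standard multilocus form, defined even
  when individual loci are monomorphic. When the between-population mean
  is zero the vectorised FST is 0 (monomorphic data carry no
  differentiation signal, and reference tables must be free of missing
  values); the scalar `pairwiseFst()` still signals the undefined case as
  `NA`.
* Net between-group p-distances subtract the average within-group
  diversity from the between-group mean, per locus and then averaged for
  the nuclear matrix; singleton groups contribute zero within-group
  diversity.

## ABC machinery and numerical choices

* **Normalization**: each statistic is scaled by its median absolute
  deviation across the reference table, with a standard-deviation fallback
  when the MAD is zero and a warned drop when both are zero. MAD is the
  robust convention of the reference ABC implementations.
* **Rejection**: the `ceiling(tolerance * N)` smallest Euclidean distances
  are retained; boundary ties break deterministically by row index.
  Epanechnikov weights `1 - (d/dmax)^2` are taken relative to the
  acceptance radius (all weights 1 when the radius is 0).
* **Model choice**: retained rows are pooled across models (normalized
  jointly) and the model label is regressed on the scaled statistics by
  multinomial logistic regression (`nnet::multinom`) with a mild L2
  penalty (decay 0.01) so that complete separation cannot destabilise the
  fit; the fit is evaluated at the observed vector. A model with no
  retained rows receives probability 0 with a warning.
* **Parameter estimation**: retained draws are logit-transformed inside
  their uniform prior bounds before any regression adjustment, which
  guarantees adjusted draws respect the bounds after back-transformation.
  Local-linear adjustment (weighted least squares, the deterministic
  default) subtracts the fitted statistic effect; the neural-net variant
  uses a single hidden layer of 5 units, weight decay 0.01, and 10
  restarts aggregated by their element-wise median, all seed-controlled.
  A degenerate (collinear) regression falls back to rejection with a
  warning. Summaries: minimum/maximum of the retained draws; weighted
  2.5%/median/97.5% by weighted quantiles; weighted mean; weighted mode as
  the peak of a Gaussian-kernel density with Silverman's bandwidth.
* **Validation**: cross-validated confusion (hard) and mean-posterior
  (soft) matrices hold each pseudo-observed row out of its table;
  the goodness-of-fit statistic is the median normalized retained
  distance, calibrated against table rows processed identically; posterior
  predictive checks resample weighted retained draws, re-simulate, and
  report per-statistic tail probabilities.

The pipeline encodes the study design: stage 1 compares models A–E at 10%
tolerance on either marker set; stage 2 — nuclear only — compares D, F and
G at 5% tolerance and runs when stage 1 supports a model with C–A gene
flow (C, D or E) under the default `stage2 = "auto"`; estimation uses 1%
tolerance. Nuclear and mitochondrial tracks are always simulated
separately, and the Z-linked inheritance class is never simulated.

## What the synthetic generator does and does not emulate

`generatePseudoObserved()` reproduces the structural features the
analysis is sensitive to: a panel of 7 autosomal loci totalling 3,711 bp
plus one 1,118 bp mitochondrial locus, 41 focal individuals (19 C, 12 P,
10 A), Bernoulli sample–locus missingness at 67.4% coverage with at least
two sequences per focal population per locus, and optional IUPAC-coded
heterozygous sites to exercise the I/O rules (injected as noise; the
statistics exclude such sites by design, so statistical tests use a rate
of 0). It makes no attempt to imitate real base composition (sequences
are biallelic A/T on an A background), rate variation among sites,
intra-locus recombination, or outgroup taxa. Passing recovery tests
therefore demonstrates the correctness and calibration of the inference
machinery under its own assumptions — not robustness to recombination,
selection or model misspecification in real data.

The "easy" preset (`easyPreset()`) used by the recovery experiments takes
mid-prior true parameters (migration rates at the upper/lower quartiles of
their shared prior so the F/G ordering holds), five fully sequenced
individuals per population, and elevated mutation rates — 2e-8 nuclear,
2e-7 mitochondrial per site per generation — so that reduced reference
tables carry measurable signal at desk scale. At these rates
deep-divergence prior draws can saturate the mitochondrial locus; the
finite-sites fallback handles this, as it does for real mitochondrial
data at comparable depths.

## Problem sizes used by the test suite

The motivating study ran 1,000,000 simulations per model; the package
reproduces that workflow at reduced, desk-scale sizes chosen once:
reference tables of 20,000–50,000 rows, 50–100 pseudo-observed datasets
for cross-validation and coverage, 2,000 replicates for the
cross-simulator comparison (against msprime, used strictly as an
independent oracle in tests), and 5,000 replicates for the closed-form
coalescent calibrations. Coverage experiments use the rejection method:
it is deterministic given the retained set and its credible intervals are
calibration-safe, whereas regression adjustment can under-cover when the
regression is locally misspecified.

## Known limitations

* No recombination within loci, no selection, no population growth or
  decline, at most three demes — these mirror the modelling scope, not
  implementation shortcuts.
* The multilocus FST uses Hudson's simple estimator; AMOVA-style
  estimators are out of scope.
* Statistic sets are configurable only as a whole (observed and simulated
  vectors always share one definition); per-statistic toggling would
  invite observed/simulated mismatch.
* The mitochondrial track rests on a single linkage group; as in the
  motivating study, its parameter estimates are correspondingly fragile.
* Discrimination between continuous-flow (F) and glacial-window (G)
  models is intrinsically subtle when `tIso` is small relative to deme
  sizes; at desk scale the stage-2 test asserts a majority ranking rather
  than near-certainty.
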