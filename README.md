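# coalABC

Coalescent simulation and Approximate Bayesian Computation (ABC) for
inferring gene flow among three closely related populations from
multilocus sequence alignments.

The package is aimed at phylogeographers working with Sanger-scale
multilocus data (a handful of nuclear loci plus a mitochondrial gene) who
want to ask: is the shallow differentiation between populations the
product of gene flow — continuous, asymmetric, or confined to glacial
periods — or only of recently shared ancestral polymorphism? Its defaults
mirror an Andean flycatcher system of three taxa (labelled *chilensis* C,
*pallatangae* P, *albiceps* A), but every component is parameterised.

## The method

Seven demographic models share the fixed topology ((C, P), A) — splits at
`T_CP < T_A` generations, constant deme sizes `N_C, N_P, N_A` — and
differ only in migration: none (A), C–P (B), C–A (C), both with a shared
rate (D), all pairs (E), both with ordered independent rates
`m_CP > m_CA` (F), and F with gene flow shut off during the last `tIso =
20,000` generations (G, the glacial-window isolation–migration model).
Priors are uniform: `N` in [10, 1e5] individuals (mitochondrial bound
2.5e4), `T_CP` in [1e4, 2e6], `T_A` in [1e6, 7e6] generations, migration
probabilities in [1e-8, 1e-4] per lineage per generation.

A compiled event-driven structured coalescent simulates multilocus data
under prior draws (infinite-sites mutation, free recombination between
loci, none within); each dataset reduces to a 13-statistic vector
(per-population *S* and π, pooled *S*, pairwise between-population
differences, pairwise Hudson F<sub>ST</sub> = 1 − π<sub>w</sub>/π<sub>b</sub>),
computed identically for observed alignments (with pairwise deletion of
IUPAC/missing symbols) and simulations. ABC then proceeds by
MAD-normalized Euclidean rejection with Epanechnikov weights: model
posterior probabilities by multinomial logistic regression on retained
rows, validated by cross-validated confusion matrices, goodness of fit
and posterior predictive checks; parameter estimation by
local-linear or neural-net regression adjustment on logit-transformed
draws, summarized as weighted quantiles, mean, and kernel-density mode.

## Worked example

Generate a pseudo-observed dataset under the isolation–migration model G
(mid-prior truth, elevated desk-scale mutation rates), run the two-stage
model selection at reduced table size, and estimate parameters:

```r
library(coalABC)
set.seed(7)

pd  <- generatePseudoObserved(easyPreset("G"))
obs <- observedStatVector(pd$dataset, markerSet = "nuclear")

rep <- runModelSelection(pd$dataset, "nuclear", nSim = 20000,
                         tolerances = c(set1 = 0.10, set2 = 0.05),
                         mu = c(nuclear = 2e-8, mitochondrial = 2e-7),
                         nPseudo = 0, nNull = 100, stage2 = "always")
print(rep)
#> Model selection (nuclear track)
#>   stage 1 (A-E, tolerance 0.1): best model D
#>      A      B      C      D      E
#> 0.0000 0.0000 0.0000 0.7608 0.2392
#>   stage 2 (D/F/G, tolerance 0.05): best model G
#>      D      F      G
#> 0.0899 0.0601 0.8500
```

Stage 1 rejects the no-flow model A outright and favours the symmetric
two-pair flow model D; stage 2 then separates D from its asymmetric (F)
and glacial-window (G) refinements and assigns the generating model G a
posterior probability of 0.85. The goodness-of-fit p-value of the winning
model is 0.76 (the observation sits comfortably inside its retained set).

```r
est <- runParameterEstimation(pd$dataset, "G", "nuclear",
                              tolerance = 0.02, method = "loclinear",
                              table = rep$stage2$tables[["G"]])
print(est)
#> Parameter estimation: model G (nuclear track), loclinear at tolerance 0.02
#>                 Ne_albiceps Ne_chilensis Ne_pallatangae    T_CP     T_A ...
#> Weighted Median       37000        68400          46600 1190000 4280000
#> Weighted 97.5%        85600        96800          92100 1920000 6850000
```

The weighted 95% intervals bracket the generating truth (`N` = 50,005 for
all three demes, `T_CP` = 1.005e6, `T_A` = 4e6, `m_CP` = 7.5e-5,
`m_CA` = 2.5e-5), with medians of the well-identified time parameters
within ~20% of it.

Reading real data instead: per-locus FASTA plus a two-column popmap TSV,
tied together by a YAML manifest —

```r
ds  <- readDatasetManifest("manifest.yaml")
obs <- observedStatVector(ds, "nuclear")
dm  <- distanceMatrix(ds, "mitochondrial")   # net between-taxa p-distances
```

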