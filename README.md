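# strainforge

High-throughput generation, curation and comparison of strain-specific
genome-scale metabolic models (GEMs) in R.

## The problem

Comparative studies of hundreds of closely related bacterial strains
increasingly start from automatically reconstructed GEMs: each strain's
network is "carved" out of a universal reaction-database model using
homology-derived reaction scores, then simulated under defined media.
Automated carving leaves systematic artifacts that distort strain
comparison — duplicate database entries, mass/charge-imbalanced
reactions, gene-less gap-filled reactions with no genomic evidence,
gene-evidenced reactions dropped for lack of connectivity, and
energy-generating cycles (EGCs) created by redundant transport variants.
strainforge provides the curation and refinement machinery around the
carving step, a constraint-based simulation suite for the downstream
comparisons, and a deterministic toy universe that makes every expected
outcome derivable by hand.

It is aimed at microbial systems biologists building strain panels
(dairy lactic acid bacteria are the motivating system), and at method
developers who need a fully controlled desk-scale substrate for
constraint-based pipelines.

## What is inside

The core is flux balance analysis on a compartmentalized stoichiometric
network: maximize the objective flux `c'v` subject to steady state
`S v = 0` and bounds `l <= v <= u` (GLPK backend, deterministic
single-threaded simplex). All comparative simulations use parsimonious
FBA: the objective is fixed at its optimum and total absolute flux
`sum(|v|)` is minimized, suppressing loop fluxes. Media follow the
standard anaerobic convention for lactococci: every non-carbon component
capped at 1 mmol/gDW/h, water and protons free, and the carbon source
bounded at a C-mol equivalent of 20 mmol/gDW/h glucose
(`120 / carbon atoms`). A strain counts as non-growing below 10% of its
reference growth rate.

Modules:

* `readSBML()` / `writeSBML()` — lossless SBML L3V1 + FBC v2 exchange;
* `parseFormula()`, `auditBalance()`, `modelStats()` — formula/charge
  bookkeeping (with R/X pseudo-elements) and model statistics;
* `findDuplicates()` / `mergeDuplicates()` / `applyPatch()` — universal
  model curation;
* `pruneGapfill()`, `restoreScoredReactions()`, `installBiomass()`,
  `refineStrain()` — post-carve refinement;
* `buildPanModel()`, `detectEnergyGeneratingCycles()`,
  `findTransportVariants()` — cohort-level curation discovery;
* `solveFBA()`, `solvePFBA()`, `maxATPYield()`, `fermentationProfile()`,
  `pflScan()`, `essentialityScan()`, `attachCasein()`,
  `catabolicCapacity()`, `restrictTransport()`, `crossfeedScreen()` —
  the simulation suite;
* `presenceMatrix()`, `reactionDistance()`, `clusterStrains()`,
  `pathwayCompleteness()` — reaction-content comparison;
* `buildToyUniversal()`, `deriveStrain()`, `generateCohort()` — the toy
  universe.

A thin command-line front end is installed at
`<library>/strainforge/exec/strainforge`
(`stats`, `balance`, `fba`, `refine`, `curate-universal`, `pan-curate`,
`compare`, `fixture` subcommands).

## Worked example

```r
library(strainforge)

u <- buildToyUniversal()
cohort <- generateCohort(6, 42, universalBuild = u)
cdm <- buildCDM("EX_glc__D_e", 6)           # glucose at 20 mmol/gDW/h
refined <- lapply(cohort$strains, function(s)
  refineStrain(s$model, u$model, s$scores, list(cdm), toyBiomassSpec())$model)

refined[[1]]
#> GEM 'LL_001': 71 metabolites, 77 reactions, 61 genes
#>   metabolic 27 | transport 25 | exchange 24 | biomass 1
#>   compartments: c, e; objective: BIOMASS_LACTO

fp <- fermentationProfile(refined[[1]], cdm)
round(fp$secretion, 3)
#>    EX_for_e     EX_ac_e   EX_etoh_e EX_lac__D_e
#>          40          20          20           0
```

Formate, acetate and ethanol in a 2:1:1 ratio with no lactate is
mixed-acid fermentation — the ATP-optimal mode, worth 3 mol ATP per mol
glucose in this network:

```r
sapply(refined, function(m)
  maxATPYield(m, buildSimplifiedMedium("EX_glc__D_e"), "EX_glc__D_e", 6))
#> LL_001 LL_002 LL_003 LC_004 LC_005 LC_006
#>    0.5    0.5    0.5    0.5    0.5    0.5
```

0.5 mol ATP per C-mol × 6 carbons = 3 ATP/glucose. Leave-one-out
essentiality on the first strain shows the amino-acid auxotrophies
(this strain cannot assimilate sulfate, so cysteine is essential) while
minerals are dispensable:

```r
essentialityScan(refined[[1]], cdm)
#>     component relative_growth essential
#> 1 EX_glu__L_e               0      TRUE
#> 2 EX_leu__L_e               0      TRUE
#> 3 EX_cys__L_e               0      TRUE
#> 4 EX_met__L_e               0      TRUE
#> 5    EX_so4_e               1     FALSE
#> 6     EX_pi_e               1     FALSE
#> 7    EX_nh4_e               1     FALSE
#> 8 EX_glc__D_e               0      TRUE
```

Reaction-content clustering separates the two generated species classes
(the pentose and lactose/galactose systems differ):

```r
pan <- buildPanModel(refined)
cutStrains(clusterStrains(reactionDistance(presenceMatrix(pan))), 2)
#> LL_001 LL_002 LL_003 LC_004 LC_005 LC_006
#>      1      1      1      2      2      2
```

See `vignettes/strainforge-methods.Rmd` for the models, conventions and
design decisions, including exactly what the toy universe does and does
not emulate.

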