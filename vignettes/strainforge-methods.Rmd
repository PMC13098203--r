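---
title: "strainforge: models, conventions and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{strainforge: models, conventions and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainforge)
```

# Scope

strainforge is a toolkit for building, curating and comparing cohorts of
strain-specific genome-scale metabolic models (GEMs), aimed at the
high-throughput setting where hundreds of closely related strains are
carved from one universal reaction-database model and then compared by
simulation. It covers:

* curation of the universal model (duplicate merging, mass/charge balance
  auditing, patch files);
* post-carve refinement of draft strain models (gap-fill pruning,
  restoration of gene-evidenced disconnected reactions, installation of a
  species-specific biomass reaction);
* pan-model construction with detection of energy-generating cycles (EGCs)
  and redundant membrane-transport variants;
* a comparative simulation suite on flux balance analysis (FBA) and
  parsimonious FBA (pFBA): fermentation profiling, pyruvate-formate-lyase
  (PFL) scans, C-mol-normalized ATP yields, leave-one-out nutrient
  essentiality, growth on a casein peptide as the amino-acid source, and
  cross-feeding screens;
* reaction presence/absence comparison with hierarchical clustering;
* a deterministic toy-universe generator that serves as the desk-scale
  test substrate for all of the above.

The carving step itself (the MILP that selects a strain subnetwork from
the universal model using homology scores) is out of scope; strainforge
consumes its outputs — a draft model plus a reaction-score table.

# The constraint-based model

A `GEM` is a compartmentalized stoichiometric network: metabolites with
chemical formula and charge, reactions with flux bounds
(mmol gDW^-1^ h^-1^) and boolean gene-protein-reaction (GPR)
associations, a sparse stoichiometric matrix $S$, and one objective
reaction. FBA solves

$$\max_v\; c^\top v \quad \text{s.t.}\quad S\,v = 0,\; l \le v \le u,$$

with the biomass pseudo-reaction as the default objective, so the optimal
objective value is the specific growth rate (h^-1^). pFBA re-solves with
the objective fixed at its optimum (relative slack $10^{-6}$) and total
absolute flux minimized via split forward/reverse variables; it is the
workhorse for all comparative simulations because it suppresses
thermodynamically meaningless loop fluxes. The LP backend is GLPK
(single-threaded, deterministic simplex). Fluxes below $10^{-6}$
mmol gDW^-1^ h^-1^ are treated as zero everywhere (secretion calls,
pruning, EGC detection): this is far above solver noise and far below any
biologically meaningful flux at the scale of these simulations.

# Simulation conventions

Media are expressed as `SimulationCondition` objects: maximum uptake
rates for exchange reactions. Following standard practice for anaerobic
lactococcal simulations, every non-carbon medium component is capped at
1 mmol gDW^-1^ h^-1^, water and protons are unconstrained, and the
carbon source is bounded at a C-mol equivalent of 20 mmol gDW^-1^ h^-1^
glucose, i.e. $120/\text{(carbon atoms)}$ — glucose 20, lactose 10,
ribose 24. Exchanges not named in a condition are closed to uptake. A
strain is called non-growing when its growth rate falls below 10% of the
reference (full-medium) rate, which guards against residual amino-acid
catabolism masquerading as growth.

ATP yields are computed by swapping the objective to an ATP-maintenance
hydrolysis reaction (atp + h2o → adp + pi + h) and normalizing its
maximal flux by carbon uptake. The yield medium contains only the
substrate, water and protons: amino acids, vitamins and minerals are
removed, both because they are unnecessary for carbon catabolism and
because a sulfur or nitrogen source would let biosynthetic proton sinks
couple to the membrane ATPase and distort the yield (see "Proton
bookkeeping" below).

The homolactate condition caps the PFL flux at 0.1 mmol gDW^-1^ h^-1^
(a trickle of acetyl-CoA remains available for anabolism); the PFL scan
sweeps the upper bound over 0.1–60 mmol gDW^-1^ h^-1^, by default in 25
log-spaced points. Growth is non-decreasing in the bound because raising
an upper bound is an LP relaxation.

The casein ("milk") condition removes free amino acids and supplies a
single synthetic average peptide instead. The peptide is normalized so 1
mol peptide ≡ 1 mol amino-acid residues, and its uptake bound defaults to
the total free-amino-acid supply of the CDM it replaces. This
residue-supply parity makes composition skew the only difference between
the two media — in particular the low cysteine fraction of casein (0.3%)
versus its share of the biomass amino-acid composition (5%), which is
what limits growth for cysteine auxotrophs. Cross-feeding screens add a
candidate product at 1 mmol gDW^-1^ h^-1^ (or raise it to 2 when it is
already a medium component); a strain consumes the product when its
uptake flux is positive and growth strictly increases.

# Curation machinery

Duplicate metabolites are grouped when they share compartment, formula
and charge and either share a database identifier or have equal
canonicalized names (lowercase, non-alphanumerics stripped — the raw
name strings of pooled models are too brittle to compare directly).
Duplicate reactions are grouped by normalized stoichiometry, where each
reaction is oriented to the lexicographically smaller of (stoich,
−stoich), so sign-flipped copies group too. Merging keeps the
lexicographically smallest id (C-locale ordering, for determinism across
platforms), ORs the member GPRs, unions annotations and widens bounds to
the union of feasible directions — merging must never remove a capability
present in either duplicate. Because merging two metabolites can make two
previously distinct reactions identical, scan and merge iterate to a
fixpoint.

The balance audit classifies every reaction: `exempt` (exchanges, sinks,
biomass), `unknown_formula` (any participant without a parsable formula —
the audit must not abort on exotic database entries, so polymeric or
parenthesized formulas fall here rather than erroring),
`proton_imbalanced` (hydrogen and charge off by the same amount — the
classic protonation-state mismatch between source models),
`charge_imbalanced`, `mass_imbalanced`, or `balanced`. Generic acyl/`R`
and unspecified/`X` groups are carried as pseudo-elements so that
R-group bookkeeping is audited like any other element. Corrections are
applied from patch files (TSV edit lists with idempotent semantics), not
fetched from databases: the provenance of every edit stays in the patch.

# Refinement of draft strain models

Carving prioritizes connectivity, which leaves two systematic artifacts:
gene-less gap-filled reactions with no genomic evidence, and
gene-evidenced reactions dropped only because they were disconnected.
`refineStrain()` runs three steps in a fixed order:

1. **Biomass installation** first, so that pruning judges fluxes under
   the final objective.
2. **Gap-fill pruning**: one pFBA per gap-fill condition; a gap-filled
   *metabolic* reaction is removed iff it carries no flux in any
   condition; a gap-filled *transport* reaction is additionally retained
   when any metabolite it moves is touched by a GPR-bearing reaction
   (transporter genes are notoriously under-annotated, so absence of a
   GPR is weak evidence against a transporter whose cargo has genomic
   support); exchanges left disconnected are dropped. Pruning must not
   change any condition's growth optimum (checked to $10^{-6}$).
3. **Restoration** last, so restored dead-ends can never be pruned: every
   universal reaction with a positive carving score that is absent from
   the model is copied in and flagged `restored_disconnected`. These
   reactions usually cannot carry flux, but they belong in reaction
   presence/absence comparisons and pathway-completeness queries.

"Carries flux" is judged on the single pFBA solution per condition.
Alternate optima could in principle route flux through a reaction that
this solution leaves idle; we accept that blindness (flux-variability
analysis would close it at considerable cost) and document it rather than
mitigate it.

Whether to prune against one condition or several is left to the caller:
`refineStrain()` accepts a list and requires flux-lessness in all of
them.

# Pan-model curation

The pan-model is the union network over a cohort (one copy per reaction
id, bounds unioned) plus a strain × reaction presence matrix. EGC
detection closes every exchange and maximizes, per energy currency, a
dissipation reaction (ATP, GTP, NADH, NADPH, FADH2 hydrolysis/oxidation
and the transmembrane proton gradient; the dissipation specs are data,
not code, so other namespaces can supply their own table). Any nonzero
dissipation with closed exchanges is energy from nothing; the pFBA
support names the offending loop. The canonical culprit in carved
cohorts — multiple variants of one transporter with different proton
stoichiometry, which together with the F-ATPase form an impossible proton
pump — is located by `findTransportVariants()`: transport reactions that
become stoichiometrically identical once protons are deleted. Which
variant to keep is a curation judgment, so the tool only detects and
reports; removal arrives as a patch.

# The toy universe

Testing this machinery requires a substrate where every expected outcome
is derivable by hand. `buildToyUniversal()` constructs a balanced
~110-reaction anaerobic core network in the BiGG namespace: PTS glucose
uptake; lumped glycolysis (the lower lump yields 1 ATP + 1 NADH per
triose phosphate); the LDH/PFL/PDH pyruvate branches with acetate
(+1 ATP) and ethanol (−2 NADH) branches; both galactose routes
(tagatose-6P via PTS, Leloir via permease); both lactose routes
(PTS + phospho-β-galactosidase operon-linked to tagatose-6P, permease +
β-galactosidase linked to Leloir); maltose PTS and ABC routes; xylose and
ribose pentose routes through phosphoketolase plus a deliberately
low-yield one-lump stand-in for the nucleotide-loop ribose bypass (it
forgoes the acetyl-phosphate ATP, halving the yield, which preserves the
"growth possible but clearly lower yield" phenotype without a ten-step
chain); sulfate assimilation to hydrogen sulfide feeding
cysteine synthesis; a leucine biosynthesis lump; the arginine-deiminase
pathway (+1 ATP per arginine, with the arginine/ornithine antiporter);
citrate lyase; a two-step synthetic dead-end storage pathway (the
restoration target); and an F1F0 ATP synthase. Four amino acids
(glutamate, leucine, methionine, cysteine) stand in for twenty: the
smallest set that exercises auxotrophy structure, casein composition skew
and amino-acid cross-feeding; casein composition tables pad the remaining
mass onto glutamate.

All metabolite formulas and charges follow the standard database
conventions, and the generator verifies that every non-exempt reaction
passes the balance audit (a residual protonation gap is closed with
cytosolic protons; any other elemental gap is a generator error). The
biomass reaction drains the four amino acids (cysteine at 5% of the
amino-acid composition) plus 60 mmol gDW^-1^ growth-associated ATP
hydrolysis. The universal model carries a generic variant that
additionally demands sulfate — installing the species-specific reaction
therefore changes medium-component essentiality, which is the property
the biomass-installation tests pin down.

Two stoichiometric anchors are derivable by hand and are asserted
exactly: glucose fermented mixed-acid yields 3 mol ATP/mol (2 glycolytic
net + 1 acetate kinase, with the NADH balanced by one ethanol per
acetate), and homolactate (PFL and PDH closed) yields 2. The Leloir lump
deliberately carries one extra ATP hydrolysis ("costed conversion"): a
plain Leloir route would be exactly ATP-equivalent to the tagatose-6P
route in this network (the PTS's PEP consumption offsets the kinase
cost), and the galactose/lactose yield split between the two strain
classes is a phenotype the suite must reproduce.

## Proton bookkeeping

The toy network models the proton gradient explicitly: fermentation
products leave by proton symport, amino acids move by uniport, the
membrane is otherwise proton-tight, and the reversible F1F0 ATPase
couples the gradient to ATP. One consequence is physiological: product
efflux contributes to the proton motive force, and on some substrates
the LP exploits this "energy recycling" (e.g. citrate catabolism yields
1.5 ATP rather than the naive 1.0). For the glucose yields the proton
budget closes exactly and the synthase carries zero flux, which is why
the 3/2 anchors are exact. The cysteine transporter is import-only:
with a reversible exporter the LP discovers a nonphysiological
"cysteine overflow" valve (sulfate assimilation as a proton/NADH sink),
which no lactococcus exhibits.

## Derived strains and cohorts

`deriveStrain()` stands in for a carving run: pathway flags remove
reaction groups and their genes; the dead-end storage pathway is withheld
despite positive scores (exercising restoration); a fixed set of
gene-less gap-filled reactions is injected (three metabolic ones that can
never carry flux, one transporter whose cargo has gene support and must
survive pruning, one disconnected exchange); the emitted score table has
positive scores exactly for the gene-evidenced reactions the strain kept.
Optionally, two transport-variant pairs (lactate and acetate uniporters
shadowing the symporters) are injected to seed EGCs; together with the
ATP synthase each pair forms a three-reaction proton pump that the EGC
detector must flag and the shipped variant-removal patch must silence.

`generateCohort()` samples pathway profiles per strain, half
"lactis-like", half "cremoris-like". The probabilities are the
generator's study conditions, chosen once to mirror the hallmark
fractions of a dairy *Lactococcus* panel: the pentose block (xylose
operon, phosphoketolase, acetyl-P kinase) fixed present in lactis-like
and absent in cremoris-like; the plasmid-borne tagatose-6P/lactose-PTS
system predominantly in the dairy-associated class (0.92 vs 0.15);
maltose-PTS absent in a fifth of cremoris-like strains (≈10% cohort-wide);
sulfate assimilation in ≈11% (cysteine auxotrophy in the rest); leucine
biosynthesis in 5%; arginine deiminase missing in ≈4%; citrate lyase in
14%. Per-strain seeds are drawn from a single master stream — consecutive
integer seeds produce correlated Mersenne–Twister streams, which visibly
distorts low-probability flags. Regeneration from the same seed is
byte-identical through to the SBML serialization (C-locale ordering,
fixed-precision number formatting).

What the toy cohort does *not* emulate: genome-scale size (≈10^2^ vs
≈10^3^ reactions), twenty amino acids and vitamin/nucleobase chemistry,
annotation noise in formulas and names, CO~2~-producing mixed-acid
stoichiometry in every strain, and the long tail of strain-private
reactions that real pan-genomes carry. Green tests therefore certify the
machinery's contracts — bound semantics, pruning/restoration exactness,
EGC detection, clustering recovery under a designed species signal — not
predictive accuracy on real reconstructions.

# Comparison

Reaction distance defaults to Jaccard on the presence matrix (the
standard metric for binary trait data; Hamming is available), and
clustering to average linkage — both configurable, since the upstream
methods literature rarely states its choices. Dendrograms are
deterministic given the distance matrix; permuting strain order permutes
leaves but not partitions. Newick export goes through `ape`.

# SBML dialect

Models are exchanged as SBML Level 3 Version 1 with the FBC v2 package:
species carry `fbc:charge` and `fbc:chemicalFormula`, flux bounds are
shared constant parameters, GPRs are gene-product association trees, and
the single active objective is declared in `fbc:listOfObjectives`.
Reaction flags (`gap_filled`, `restored_disconnected`, `biomass`,
`exempt_from_balance`), subsystems and database annotations ride in
`<notes>` under fixed `strainforge:` keys, which keeps a write/read round
trip lossless while remaining inert for other FBC parsers (verified
against cobrapy in the test suite). Level 2 input and RDF/MIRIAM
annotation blocks are not supported.

# Problem sizes and numerical choices

The shipped test suite and the acceptance script run everything on toy
cohorts: 40 strains for the contract checks, 100 strains for the
reported cohort fractions, a 20-strain variant-injected subcohort for the
EGC sweep, 100 randomized corruption trials for the balance audit and
1000 random formulas against an independent character-walk parser. At
~85 reactions per strain a pFBA solves in about a millisecond, so the
whole suite stays in the tens of seconds on one CPU. Tolerances:
$10^{-6}$ for flux zero/growth preservation/steady-state residuals,
relative pFBA objective slack $10^{-6}$, unconstrained-exchange bound
1000 mmol gDW^-1^ h^-1^. TSV/CLI outputs round fluxes to 6 decimals;
in-memory solutions are never rounded, so residual invariants remain
meaningful.

# Known limitations

* Single-solution flux calls (no FVA): pruning and secretion calls can
  be blind to alternate optima.
* No thermodynamic, kinetic or proteome constraints; the PFL scan
  reproduces the homolactic/mixed-acid shift mechanically via a bound,
  not its regulatory cause.
* The casein peptide is a single average species; peptide-length and
  transport-specificity effects are out of scope.
* Community simulation (joint growth of multiple strains) is out of
  scope; the cross-feeding screen evaluates producer and consumer roles
  strain by strain.
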