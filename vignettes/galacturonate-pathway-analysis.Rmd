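---
title: "Stoichiometric dissection of D-galacturonate fermentation pathways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stoichiometric dissection of D-galacturonate fermentation pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(galufer)
```

## The problem

D-galacturonate, the main monomer of pectin, is fermented anaerobically by
bacteria through the galacturonate-isomerase (adapted Entner–Doudoroff)
pathway: galacturonate → tagaturonate → fructuronate → mannonate →
2-keto-3-deoxygluconate (KDG) → KDPG → pyruvate + glyceraldehyde-3-phosphate.
The upper pathway invests 1 ATP and 1 NAD(P)H per substrate; lower glycolysis
returns 2 ATP and 1 NADH, so the route to two pyruvate is redox-cofactor
neutral with a net ATP yield of 1 mol (mol galacturonate)⁻¹. Because
fermentative metabolism must balance its redox cofactors internally, this
accounting tightly constrains which product profiles a given pathway can
sustain — and that constraint is what lets chemostat stoichiometry, proteome
detections and enzyme assays discriminate between candidate pathways.

A heterofermentative *Lactobacillus* isolate producing near-equimolar lactate
and acetate from galacturonate poses exactly this discrimination problem. The
canonical pathway alone cannot make acetate at all; extended with a
hypothetical PDH/phosphotransacetylase/acetate-kinase branch it can, but the
proteome must then contain the full lower pathway. The alternative is a
hybrid route in which mannonate is phosphorylated by a mannonate kinase,
epimerized to 6-phosphogluconate by a 6-phosphomannonate 2-epimerase, and
dissimilated through the phosphoketolase pathway — a redox-cofactor-neutral
conversion of galacturonate to ribulose-5-phosphate and CO₂, and onward to
1 lactate + 1 acetate + 1 CO₂ with a net ATP yield of 2. This package encodes
all of these as explicit reaction networks and implements the quantitative
arguments end to end.

## Reaction networks and element balancing

Each pathway variant ships as a human-readable reaction table
(`inst/extdata/pathways/`). Species are registered compounds with elemental
formulas; organic acids are booked as neutral, fully protonated species
(molar yield ratios are unaffected by protonation state, so charge
bookkeeping is deliberately omitted). Cofactor pairs (ATP/ADP, NAD⁺/NADH,
NADP⁺/NADPH) are net deltas per unit flux, not species, so pathway solutions
need no regeneration pseudo-reactions. H₂O and inorganic phosphate are
closure species: their coefficients are solved per reaction from the O and P
balance, because pathway diagrams conventionally omit them and no carbon or
redox claim depends on them.

Element conservation is enforced on load: one NAD(P)H carries 2 H (hence 2
electron equivalents), one ATP carries an HPO₃ phosphoryl group (0 electron
equivalents). A consequence checked as a property test is that any
element-closed reaction also closes the degree-of-reduction balance:

```{r}
p <- build_pathway("hybrid_isomerase_pk")
check_reaction_balance(p$reactions[["GND"]])
```

Degrees of reduction use the Roels reference set (CO₂, H₂O, NH₃; γ_N = −3),
giving galacturonate γ = 20, lactate 12, acetate 8, and biomass
(CH₁.₈O₀.₅N₀.₂) 4.2 per C-mol. The reference convention for nitrogen is a
genuine choice — with a different N reference the biomass γ lies between 4.2
and 5.0 — and the Roels convention is the field's default, so it is the
package default; closure fractions shift by well under one percentage point
for the ammonium-grown cultures modelled here.

Two encoding choices worth recording: the ribulose-5-P → xylulose-5-P step is
encoded as a 3-epimerase (EC 5.1.3.1) because that is the chemistry required
to feed phosphoketolase, even though annotation tables for this organism
label the *araD* product with the L-ribulose-5-phosphate 4-epimerase EC
number; and tagaturonate 3-epimerase is registered once under the key
`uxaE` although the literature alternates between UxaE and UxuE for the same
activity.

## Net conversions, ATP and redox deltas

`net_conversion()` solves the internal-metabolite steady state
`S_int v = 0` with unit substrate uptake by exact QR factorization — the
shipped networks are trees, so the flux ray is unique and the Table-scale
assertions are deterministic rather than tolerance-dependent. Branch points
(e.g. the pyruvate split between LDH and PDH in the extended canonical
variant) deliberately raise an "underdetermined" error naming the free
reactions; free fluxes are only ever pinned by explicit target yields in
`product_profile_feasible()`, never resolved silently.

```{r}
net_conversion(build_pathway("canonical_isomerase"), truncate_at = "pyruvate")
net_conversion(p)  # hybrid: lactate + acetate + CO2, +2 ATP, redox-neutral
```

`product_profile_feasible()` poses the discrimination question as a linear
feasibility problem: steady state, unit uptake, irreversibility, each target
yield within a tolerance window (default 0.05 mol/mol — "near-equimolar" has
no published numeric definition, so it is an explicit parameter), optionally
net NAD(P)H = 0. The solver works on the affine solution set: with zero or
one degree of freedom (all shipped variants) the answer is exact interval
arithmetic; higher-dimensional branch spaces fall back to a phase-1 linear
program. Infeasibility returns a certificate naming the violated
constraints — for the canonical variant versus equimolar lactate/acetate,
that acetate is structurally unreachable.

The hybrid pathway's +2 ATP yield is never asserted from literature (no
source prints it); it is confirmed in the tests against an independent
symbolic-summation oracle that adds up the reaction equations along the
unit-flux path without any linear algebra.

## Chemostat reconciliation

`yields_from_rates()`, `biomass_yield()`, `carbon_balance()` and
`electron_balance()` implement the standard macro-chemical accounting:
yields are rate ratios (reported at 2 decimals by default, the precision of
published chemostat tables); the biomass formation rate comes from the
steady-state identity μ = D and the biomass C-mol mass of 24.63 g
(ash-free; no ash data exist for this organism), with an explicit
`biomass` rate column overriding it; recoveries are carbon- and γ-weighted
rate sums over products plus biomass divided by the substrate term. On the
packaged chemostat fixture the yields are 0.87 (acetate), 0.75 (lactate) and
1.04 (CO₂) mol/mol and the balances close at 0.968 (carbon) and 0.961
(electrons).

The substrate molar mass defaults to the free acid (194.14 g/mol). Note that
D/( |q_s|·M ) on the fixture gives a biomass yield of 0.097 g/g whereas the
published value is 0.09 g/g — the original value was presumably computed from
measured dry weights and residual substrate rather than from the rounded
rate ratio. The package reports the computed value and makes no attempt to
reproduce 0.09.

`estimate_mu_batch()` fits ln(OD) against time over a user-supplied window.
Automatic exponential-phase detection was considered and rejected: no
tabulated batch data exist to validate it against, so the window is an
explicit argument.

## Proteome evidence

`pathway_completeness()` maps reactions onto detected proteins through an
evidence map. Detection is binary presence — the upstream identification
pipeline has already applied its two-unique-peptide acceptance rule, so no
spectral-count threshold is re-applied here. A reaction is covered when any
mapped paralog is detected. The two novel enzymes (mannonate kinase,
6-phosphomannonate 2-epimerase) carry candidate-tier evidence (gluconate
kinase homologs and an epimerase candidate of unresolved function): they are
reported but never counted toward the completeness fraction, which is
detected/(detected + not-detected) over confirmed-tier reactions only.

On the packaged detection fixture, exactly the three lower-pathway reactions
(mannonate dehydratase, KDG kinase, KDPG aldolase) of the canonical variant
are missing (core completeness 3/6 = 0.5) while every phosphoketolase-route
reaction is covered (completeness 1.0) — the absence argument that rejects
the lower canonical pathway.

`percentile_rank()` uses the strictly-below fraction with mean tie handling
(the source of the "above the 75th percentile" claim states no convention;
this one reduces to the strictly-below fraction for unique counts and is
invariant under monotone transformations of the counts).

## Enzyme kinetics

`fit_kinetics()` fits v = V·S/(K+S) (or the substrate-inhibition form
v = V·S/(K + S + S²/K_i), which peaks at S* = √(K·K_i)) directly by
Levenberg–Marquardt least squares with positivity bounds — never a
Lineweaver–Burk linearization, which biases both parameters. Starting values
are V = max rate, K = S nearest half-max, K_i = 10·max S. Fits of the plain
Michaelis–Menten model to inhibited data leave systematically negative
residuals at high substrate; this is surfaced as a mismatch flag, and fits
can be tagged "apparent" for assays without demonstrated coupling-enzyme
excess (the situation for the mannonate-kinase assay, whose K_M of 0.4 mM is
only an estimate for that reason).

## Synthetic data: what it emulates and what it does not

The generators produce every input type the analysis consumes, seeded and
bit-reproducible (Mersenne–Twister, seed recorded in each output's
attributes). Defaults are the study conditions: hybrid pathway, D = 0.13 h⁻¹,
biomass yield 0.09 g/g, batch μ_max = 0.20 h⁻¹ on 3.3 g/L substrate,
rate noise CV 0.02 (matching the ~1–3% mean deviations of replicate
chemostat measurements), kinetics truth V_max = 0.24 μmol mg⁻¹ min⁻¹ and
K_M = 10 mM with additive noise of 5% of V_max on a 12-point substrate grid
spanning 0.1–10 × K_M (the span needed to identify both parameters), and
log-normal background spectral counts. Noise structures — multiplicative
Gaussian on rates and OD, additive Gaussian on kinetic rates — are the
simplest forms consistent with the reported dispersions; nothing stronger is
claimed for them. A Monod K_S of 0.5 mM is assumed for batch simulations
(no measured value exists; substrate-limited growth at D = 0.13 h⁻¹ with
μ_max = 0.20 h⁻¹ requires K_S well below the feed concentration).

`gen_chemostat()` constructs rates that close both balances exactly before
noise: substrate uptake follows from D and the true biomass yield, biomass
carbon drains at the dilution rate, and — because biomass (γ 4.2 per C-mol)
is more reduced than galacturonate (γ 20/6 per C-mol) — the anabolic
electron demand is met by diverting a small, carbon-neutral amount of
lactate to acetate + CO₂ (an oxidative-decarboxylation-equivalent shift of
δ = (4.2 − 20/6)·q_x/4). Noise-free tables therefore reconcile to carbon
and electron recoveries of exactly 1.0, at the cost of the lactate yield
sitting slightly below the acetate = CO₂ yield rather than exactly equal to
it; a strictly proportional 1:1:1 scaling cannot close the electron balance,
and exact closure is the invariant the downstream tests rely on.

What the generators do *not* emulate: substrate and maintenance transients,
measurement autocorrelation, proteome compositional biases, coupled-assay
lag phases, or any population heterogeneity. Passing the recovery tests
therefore demonstrates correctness of the estimators under the stated noise
models, not robustness to real-data pathologies.

## Problem sizes and numerical choices

Element-balance tolerance is 1e-6 absolute per element; steady-state and
feasibility tolerances are 1e-9; reported recoveries round to 3 decimals and
yields to 2. The stochastic recovery checks use 100 seeds each for the batch
growth-rate (window 2–14 h) and kinetics fits, and 40-seed unbiasedness
checks elsewhere; batch time courses integrate 61 output points over 30 h
with `deSolve::lsoda` at rtol 1e-10. These sizes keep the full suite around
ten seconds while leaving the stochastic assertions well-powered.

## Known limitations

No charge/proton balancing, no thermodynamics, no genome-scale model import,
no yield-optimizing FBA or elementary-mode enumeration, no statistical data
reconciliation (measurement-error-weighted balancing), and no attempt to
model the enrichment ecology. The feasibility solver is exact only up to one
branch degree of freedom; beyond that it relies on a dense phase-1 LP that
is adequate for hand-built networks, not genome-scale ones.
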