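---
title: "Virtual tumor-cell avatars: model, protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual tumor-cell avatars: model, protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virtumor)
```

## The modeling idea

`virtumor` simulates a cancer cell line as a deterministic reaction network.
A control network represents a non-transformed epithelial cell: species
(proteins, active forms, complexes, metabolites) produced and consumed by
reactions until they attain steady-state concentrations. A cell line's
genomic profile — per-gene aberrations such as activating mutations, copy
gains, overexpression or knockdown — is overlaid on the control network as
multiplicative edits of the relevant reaction nodes, producing a
"simulation avatar" of that line. A drug is one more perturbation: a
dose-dependent multiplicative inhibition (or activation) of its target
reaction nodes. Phenotype indices summarize the state of the network, and
the change of those indices under treatment yields a sensitive/resistant
call that can be compared with in vitro screening data.

Everything is deterministic: the same inputs always produce bitwise
identical trajectories. Randomness enters only through the synthetic panel
generator, which takes a mandatory seed.

## The three-state protocol

1. **Control state** — the untriggered network is integrated for 50,000
   simulated seconds, by which time all species have reached steady state
   (the package checks a relative-rate residual and raises an error if the
   control phase does not converge).
2. **Disease state** — the avatar's genetic perturbations are applied and
   the system is integrated for a further 125,000 s to its new steady
   state.
3. **Treatment state** — the drug is applied at a constant post-ADME dose
   and the system is integrated for a further 200,000 s.

Percent change is scored treated-phase-end against disease-phase-end — the
drug's effect on the diseased system, not on the control. Cumulative phase
ends sit at 50,000 / 175,000 / 375,000 s under the defaults. The drug level
is held constant for the whole treatment phase. Because all phases are
deterministic, the disease state can be computed once per avatar and shared
across drugs and doses; `doseResponse()` and the panel runners do exactly
that, and a regression test asserts the branch-vs-recompute difference is
below 1e-9.

## Phenotype indices and the sensitivity rule

* **Proliferation** — weighted mean of the active CDK–cyclin complexes
  CDK4–CCND1, CDK2–CCNE, CDK2–CCNA and CDK1–CCNB1.
* **Survival** — weighted mean of AKT1 (its active, phosphorylated form),
  BCL2, MCL1, BIRC5, BIRC2 and XIAP.
* **Apoptosis** — weighted mean of BAX, CASP3 (active), NOXA and CASP8
  (active).
* **Viability** = Survival / Apoptosis.
* **Relative growth** = (Survival + Proliferation) / 2, the proxy for
  metabolic-activity viability assays.

Weights default to uniform within each index; `optimizeWeights()` is an
opt-in deterministic grid search (step 0.1 on the simplex, lexicographic
tie-break) that maximizes Spearman correlation with an experimentally
reported trend. AKT1, CASP3 and CASP8 contribute through their active forms
because the signaling readout is activity, not abundance.

A cell line is **sensitive** to a drug when the chosen index decreases by
strictly more than 20% from the disease baseline; a change of exactly −20%
is resistant (the resistant rule reads "decreases by less than the
threshold", taken inclusive of equality, so the boundary is exact and
tested). Which index governs the call is a configuration flag
(`simulationProtocol(index_used = ...)`); the default is relative growth,
since that is the index the screening threshold is phrased against, while
viability is also computed and reported for every run — the dose-response
figures in this problem domain are usually drawn on viability.

## Genetic perturbations

Each mapped gene resolves to a network species with registered synthesis
and activity reactions. The mapping of aberration kinds to edits is:

| kind | edit | default magnitude |
|---|---|---|
| activating_mutation | activity reactions × m | 5 |
| loss_of_function | activity reactions × 1/m | 5 |
| overexpression / copy_gain | synthesis reactions × m | 3 |
| knockdown | synthesis reactions × 1/m | 5 |
| deletion | synthesis reactions × 0.01 | fixed floor |

Magnitudes are dimensionless fold factors and are deliberately treated as
free calibration parameters: expression data rarely pins down how dominant
a pathway is, which is exactly what the alignment step estimates. Defaults
are chosen so a single perturbation shifts indices by roughly 10–50%.
Multiple perturbations compose multiplicatively, so avatar creation is
order-independent. Genes without a mechanistic counterpart in the reduced
network (currently RUNX3) are declared unmapped and ignored with a logged
notice rather than guessed.

## Drugs

A drug is a list of targets, each a node (species with registered activity
reactions, or a reaction id) with an action, node potency `K`, maximal
fractional effect `Emax` and Hill exponent. At dose `d` an inhibited node's
`rate_scale` is multiplied by `1 − Emax·dⁿ/(dⁿ + Kⁿ)`. All built-in drugs
use `K = 1` a.u., so a relative dose of 1.0 stands in for the 1 µM in
vitro screen; absolute potencies are not calibrated. `Emax` defaults to
0.95 (0.99 for the irreversible-type EGFR/ERBB2 inhibitor BIBW2992, which
is modeled as reversible with a high ceiling). The library covers fourteen
agents from EGFR-family, MEK, SRC/ABL and multi-RTK inhibitors to the
CDK4/6–cyclin D1 inhibitor, the proteasome inhibitor, mTORC1, COX2 and
HMG-CoA-reductase inhibitors; an external JSON can extend or override
entries by name.

## The reduced reference network

The network (79 species, ~130 reactions) is a desk-scale reconstruction:
pathway membership follows the cancer-signaling canon, but the topology
details and all kinetic parameters are the package's own choices — no
proprietary parameterization stands behind them, and the model metadata
says so. Blocks: RTKs (EGFR, ERBB2, MET, PDGFR, VEGFR, KIT, IGF1R),
SRC/ABL, RAS–BRAF–MEK–ERK, PI3K–AKT–mTOR, IL6–JAK–STAT3, NF-κB with
proteasome-mediated IκB turnover, p53→NOXA/BAX, the apoptosis/survival
proteins, the cyclin/CDK machinery with CDKN2A/CDKN2B and RB1-gated E2F,
COX2→PGE2, the mevalonate/HMGCR axis gating RAS activation (prenylation),
and CDH1 adherens restraint of ERBB2.

Design choices that carry the biology the package needs to express:

* **Two response-curve regimes.** Trunk couplings (RTK→RAS/PI3K→effectors)
  run with a half-effect constant far above their operating level, i.e.
  effectively linear. A fractional flux cut at a drug's target then
  propagates essentially undamped, and what decides a drug's consequence
  for an avatar is the *share* its pathway holds of an index's drive. The
  BRAF→MEK step is the deliberate exception: saturable (Hill 2, half-effect
  at the wild-type operating point), so a constitutively active BRAF sits
  on the flat shoulder. That single nonlinearity yields both directions the
  retrospective panel requires: MEK inhibition still cuts the step
  proportionally (BRAF mutants, with their larger ERK-driven proliferation
  share, lose more), while upstream EGFR/ERBB2 inhibition no longer reaches
  ERK in the mutant (lapatinib resistance).
* **INK4-style CDKN2A/CDKN2B.** p16/p15 activity inhibits CDK4–cyclin D1
  complex formation. Their loss multiplies the CDK4–CCND1 level and with it
  the share of the proliferation index that any cyclin-D1-directed drug can
  reach — the common mechanism behind the CDKN2A sensitization to
  erlotinib, dasatinib, bortezomib and the CDK4/6 inhibitor.
* **Cyclin D1 integrates four routes.** ERK (saturable at constitutive-MAPK
  levels, so a mutant BRAF does not wash the other routes out), NF-κB
  (steep, Hill 2 — the proteasome-inhibition lever), mTOR, and an
  AKT-gated degradation route (the GSK3β axis: PI3K/AKT inhibition
  accelerates cyclin D1 turnover). The last gives RTK-family drugs a
  proliferation channel that works even in MAPK-decoupled (BRAF-mutant)
  backgrounds.
* **p27 (CDKN1B) is proteasome-turned-over** and restrains all CDK–cyclin
  complexes, so proteasome inhibition arrests the cell cycle in addition
  to stabilizing IκB (survival down), NOXA and p53 (apoptosis up).
* **Buffered subunit pools.** CDK4/CDK2/CDK1 pools and cyclin turnover are
  degradation-dominated, so complex abundance tracks cyclin abundance
  linearly. Without this, free-kinase competition produces rebound
  artifacts in which the genotype with the *larger* complex pool responds
  *less* to a drug — an integration-tested failure mode of early designs.
* **CDH1 and MET act through ERBB2.** CDH1 activity restrains ERBB2
  activation (loss derepresses it); MET transactivates ERBB2 with only a
  weak direct line to RAS/PI3K. Both are minimal mechanisms consistent
  with the reported association directions.
* **Mevalonate gates RAS.** HMGCR inhibition lowers the mevalonate pool
  that multiplies every RAS activation route — the statin lever.

Default kinetic scales: protein pools synthesize at 0.1 a.u./s and decay at
0.01 /s (pool ≈ 10 a.u.); active forms deactivate at 0.25 /s with a small
0.002 /s loss, keeping the active branch from draining the pool; active
species sit at ~0.2–1 a.u. so the modifier curves stay in their linear
regime. All amounts are dimensionless a.u.; time is the simulated second.

## Avatar alignment

Expression data does not reveal which pathway dominates a given line, so
avatars are calibrated against observed responses to three alignment drugs
— erlotinib probes EGFR-pathway dominance, sorafenib the MEK/ERK arm,
dasatinib SRC signaling. `alignAvatar()` runs a deterministic coordinate
descent: per-perturbation magnitude multipliers scan a 9-point log grid on
[1/10, 10], in fixed gene order, for at most three sweeps. The objective is
lexicographic: first match the observed sensitive/resistant calls, then
minimize squared error on observed percent changes, then stay closest to
the unadjusted magnitudes. The search is grid-based because the call
component of the objective is piecewise constant; a gradient method would
see zero slope almost everywhere. Only magnitudes move — never the set of
perturbed genes — and the fitted profile is locked (immutable) before
prospective use. Mismatches that survive the optimum are reported together
with the pathway block the drug probes, mirroring the alignment failures
that occur with real lines; they are never silently absorbed.

## Association testing and concordance

`testAssociation()` reproduces the mutant-versus-wild-type design: for
each named line the three-state protocol runs on the parent profile and on
the variant with the tested aberration removed (everything else retained).
A sensitizing association is reproduced in a line when the parent's
percent change is more negative than the variant's by at least ε = 1
percentage point — the margin that separates real directionality from
integrator noise; resistance-conferring is the reverse. An association is
reproduced when all tested lines agree (a majority mode exists for
stress-testing). `agreementStats()` keeps exact integer tallies and exact
ratios, rounding only when printed.

The bundled fixtures encode the main-text subset of the retrospective
panel: ten associations with the cell-line lists the figure panels name.
The per-line profiles are *synthetic reconstructions* — each line carries
exactly the aberrations those panels attribute to it, at default
magnitudes, and lines named `SYN-*` stand in for associations whose line
lists were never printed. The headline tallies (22 of 25; 61 of 80) are
encoded as record sets so the percentages are always produced by counting,
never hard-coded.

## The synthetic panel generator

`generatePanel()` emulates a prospective screen without any external data:
seeded random profiles (2–5 perturbations per line, oncogene
activation/overexpression and suppressor loss, magnitudes log-uniform on
[2, 8]), ground-truth calls computed by simulating every avatar against
the drug panel, and an "observed" table equal to the truth except for
seeded random call flips (default probability 0.1). What passing tests on
this generator show is that the pipeline is self-consistent and that the
agreement statistics behave binomially — not that the reduced network
predicts any real cell line; real expression profiles, measurement noise
in viability assays and inter-replicate variability are outside what the
generator emulates.

## Numerical choices

* Integration: `deSolve::lsoda` (stiff-capable), rtol = 1e−6,
  atol = 1e−9, ≥ 100 samples per phase. Trajectories are deterministic and
  the integrator is tested against the closed form of the linear
  synthesis–degradation ODE to 1e−6 relative error over 50,000 s.
* Steady state: converged when `max_s |ds/dt| / max(|s|, 1e−6) < 1e−6`,
  checked every 1,000 simulated seconds.
* Non-negativity: rates are evaluated on states clamped at zero; an
  undershoot within [−atol, 0) is clipped to zero with a logged warning,
  anything below −atol aborts. Linear conservation laws are preserved to
  better than 1e−8 relative drift over 100,000 s (the multistep integrator
  conserves them to round-off).
* IC50: log-linear interpolation of the first −50% crossing of the
  dose-response curve; undefined (NA) when the curve never crosses. No
  four-parameter logistic fit is attempted.
* Ties: `optimizeWeights` breaks ties lexicographically in grid
  enumeration order; `alignAvatar` prefers multipliers closest to 1.
* Problem sizes: the bundled analyses run the 79-species network; the
  retrospective panel is 10 associations over 18 lines (~70 three-state
  runs, sharing one control phase), and the synthetic prospective panel is
  40 lines × 10 drugs sharing each line's disease state.

## Known limitations

The network is a reduced reconstruction: absolute index values and IC50s
are not calibrated to any assay, and only *directions* and *calls* are
meaningful. Several biological axes named in the field's full-scale models
(autophagy, ER/oxidative stress, DNA-damage repair, microenvironment,
angiogenesis) are absent because no in-scope drug or association touches
them. Pharmacokinetics is out of scope — doses are post-ADME
concentrations by assumption. Drug effects are constant over the treatment
phase; covalent/irreversible binding is approximated by a high `Emax`.
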