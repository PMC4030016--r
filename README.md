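# virtumor

Deterministic virtual tumor-cell simulation for drug-sensitivity
prediction in R.

`virtumor` is for computational biologists who want a mechanistic,
fully-inspectable counterpart to screening-based drug-response prediction:
it simulates a cancer cell line as a reaction network ("avatar"), applies
drugs as perturbations of their target reaction nodes, and classifies the
line as sensitive or resistant from the change of phenotype indices.

## The model in brief

A control signaling/cell-cycle network (79 species, ~130 reactions:
RTK–RAS–MAPK, PI3K–AKT–mTOR, SRC/ABL, JAK–STAT3, NF-κB/proteasome,
p53/apoptosis, cyclin–CDK with CDKN2A/2B and RB1–E2F, COX2, mevalonate,
CDH1) is integrated to steady state. A cell line's aberrations act as
multiplicative edits of reaction nodes: for gene *g* with fold factor *m*,
overexpression scales its synthesis reactions by *m*, an activating
mutation scales its activity reactions by *m*, knockdown by 1/*m*, and so
on. A drug with target potency *K* and maximal effect *E*max at dose *d*
scales each inhibited node by 1 − *E*max·*d*ⁿ/(*d*ⁿ + *K*ⁿ).

The simulation protocol has three states: control (50,000 s), disease
(perturbations overlaid, 125,000 s) and treatment (constant dose,
200,000 s). Five indices are scored at each phase end:

* Proliferation = weighted mean of CDK4–CCND1, CDK2–CCNE, CDK2–CCNA,
  CDK1–CCNB1;
* Survival = weighted mean of AKT1 (active), BCL2, MCL1, BIRC5, BIRC2,
  XIAP;
* Apoptosis = weighted mean of BAX, CASP3 (active), NOXA, CASP8 (active);
* Viability = Survival / Apoptosis;
* Relative growth = (Survival + Proliferation) / 2.

A drop of the chosen index by more than 20% from the disease baseline
calls the line **sensitive**; otherwise **resistant**. Avatars can be
calibrated ("aligned") against observed responses to erlotinib, sorafenib
and dasatinib before prospective prediction, and mutant-versus-wild-type
variant pairs reproduce mutation–drug association directions.

See the methods vignette (`vignettes/virtual-tumor-avatars.Rmd`) for the
full model description and design rationale.

## Worked example

```r
library(virtumor)

net  <- buildReferenceNetwork()
prof <- cellLineProfile("EGFR-dependent",
                        data.frame(gene = "EGFR", kind = "overexpression",
                                   magnitude = 3))
r <- runThreeState(net, prof, getDrug("erlotinib"), dose = 1)
round(r$percent_change, 2)
#> proliferation        survival       apoptosis       viability relative_growth
#>        -31.28          -16.25            0.27          -16.48          -20.10
r$call
#> [1] "sensitive"
```

An avatar overexpressing EGFR 3-fold loses 20.1% relative growth at the
reference dose (1.0 a.u. ≈ the 1 µM in-vitro screen) of the EGFR inhibitor
— just past the 20% threshold, so the call is sensitive; proliferation
(−31%) responds more strongly than survival (−16%), and apoptosis is
essentially untouched. A dose-response curve over a log grid:

```r
dr <- doseResponse(net, prof, getDrug("erlotinib"),
                   doses = 10^seq(-2, 3, length.out = 11))
round(dr$responses, 1)
#>  [1]  -0.4  -1.1  -3.4  -9.1 -20.1 -32.0 -38.9 -41.7 -42.7 -43.0 -43.1
dr$ic50
#> [1] NA
```

The response saturates at −43% (bounded by the drug's Emax = 0.95), so the
−50% level is never crossed and the IC50 is reported as undefined.

The retrospective association panel (ten mutation–drug directions tested
as parent-vs-wild-type-variant pairs over the named cell-line fixtures):

```r
pan <- runRetrospectivePanel(net, studyFixture("garnett_main_text"),
                             studyFixture("garnett_line_profiles"))
pan$stats
#> AgreementStats: 10/10 matched (100.00%)
```

A command-line front end over the same functions lives in
`inst/scripts/virtumor-cli.R` (subcommands `blocks`, `simulate`,
`dose-response`, `align`, `retrospective`, `generate-panel`, `export`).

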