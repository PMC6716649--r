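# lynchcea

Cost-effectiveness modelling of reflex testing for Lynch syndrome (LS) in
women newly diagnosed with endometrial cancer (EC), from the perspective of
a public healthcare payer.

## The problem

Around 3–4% of EC probands carry a constitutional pathogenic variant in a
DNA mismatch-repair gene (*MLH1*, *MSH2*, *MSH6*, *PMS2*). Identifying them
at cancer diagnosis ("reflex" tumour-based triage) lets services offer
biennial colonoscopic surveillance to the proband and, through cascade
predictive testing, to her relatives — preventing colorectal cancer (CRC)
deaths at the price of tumour tests, genetic counselling, germline testing
and decades of colonoscopies. This package implements a decision-analytic
model of six strategies:

| Strategy | Triage |
|---|---|
| `NO_TESTING` | none (comparator) |
| `IHC` | mismatch-repair immunohistochemistry |
| `IHC_METH` | IHC, then *MLH1*-methylation testing of dMLH1 tumours |
| `MSI` | microsatellite instability testing |
| `MSI_METH` | MSI, then *MLH1*-methylation testing of MSI tumours |
| `DIRECT` | direct referral of every proband to genetic counselling |

## The model

A **decision tree** enumerates each proband's diagnostic pathway exactly:
tumour test (sensitivity/specificity/failure rate), staining-pattern split,
methylation triage, counselling attendance (55%), test acceptance (90%),
and diagnostic germline testing (sensitivity 90%, specificity 100%),
classifying probands as confirmed LS, putative LS (PLS) or discharged.
Relatives of confirmed probands receive perfect-accuracy predictive testing
(carrier probability ½); relatives of PLS probands are offered surveillance
unresolved.

A **monthly-cycle Markov cohort model** (states: alive without CRC, CRC
stage I–III, CRC stage IV, dead of CRC / EC / other causes) accrues each
person's lifetime discounted costs and QALYs to age 100, with mid-cycle
transitions and half-cycle reward accrual. Surveillance halves-or-better
LS CRC incidence (hazard ratio `h`, applied inversely to the unsurveilled)
and shifts stage at diagnosis; LS stage I–III CRC mortality carries a
hazard ratio of 0.66. Utilities are age/sex population norms, scaled by
0.79 in stage IV CRC. Costs (2016/17 GBP) cover testing, counselling,
colonoscopies every 2.1 years while surveillance is active, and a one-off
CRC management cost at incidence.

The **cost-effectiveness engine** computes, for a population of 1000
probands plus 6000 relatives, incremental cost-effectiveness ratios
(ICER = ΔC/ΔQ), strict and extended dominance, the fully incremental
frontier, net monetary benefit (NMB = λ·ΔQ − ΔC at λ = £20 000/QALY) and
cost-effectiveness acceptability curves; plus probabilistic sensitivity
analysis (PSA), one-way sensitivity analysis with tornado ordering,
proband-age heterogeneity (40–85) and an age-threshold testing-policy
analysis. A bivariate random-effects meta-analysis module (Reitsma-type,
logit-normal approximation) reproduces the evidence synthesis used to pool
test accuracy, and a synthetic-data module generates every tabulated input.

All tabulated natural-history inputs (life tables, incidence and survival
schedules, CRC costs, age distributions) are *synthetic fixtures* —
registry-shaped stand-ins for sources that cannot be shipped — so absolute
results are illustrative; the printed-evidence parameters (test accuracy,
uptake, unit costs, discounting) are the published values. See
`vignettes/model-methods.Rmd` for what is and is not established by a
green test.

## Worked example

```r
library(lynchcea)
params <- load_parameters()          # packaged base case (proband age 60)
res    <- evaluate_strategies(params, relative_ages = "weighted")
frontier(res)
```

```
    strategy     cost    qaly icer_vs_comparator_3sf       frontier_label fully_incremental_icer_3sf
1 NO_TESTING  9654201 99573.5                     NA           COMPARATOR                         NA
2        IHC 11698385 99626.0                  38900          ON_FRONTIER                     121000
3   IHC_METH 10422552 99615.5                  18300          ON_FRONTIER                      18300
4        MSI 11548611 99623.4                  38000 EXTENDEDLY_DOMINATED                         NA
5   MSI_METH 10533602 99612.8                  22400            DOMINATED                         NA
6     DIRECT 10427534 99615.2                  18500            DOMINATED                         NA
```

Reading: for 1000 probands and 6000 relatives, IHC with methylation triage
costs £768k more than no testing and gains 42 QALYs — £18 300 per QALY,
cost-effective at £20 000/QALY and the only cost-effective testing
strategy; MSI is extendedly dominated and MSI-with-methylation and direct
referral are dominated, matching the published qualitative pattern.

Single pathways are available directly:

```r
proband_pathway("IHC_METH", "MSH2", params)
#> <pathway> IHC_METH / MSH2
#> LS_CONFIRMED          PLS   DISCHARGED
#>     0.421320     0.046813     0.531867
#>   expected testing cost: GBP 832.47
```

Age matters: `age_heterogeneity(params)` shows the incremental NMB of
IHC_METH versus no testing falling strictly with proband age and turning
negative in the early 60s, and `age_threshold_policy(params)` shows a
test-everyone-up-to-age-T policy maximising economic value for T between
60 and 65 while remaining worthwhile even at T = 80.

A command-line driver mirrors the R API:

```sh
Rscript inst/cli/lynchcea run --mode base --out results/ --seed 1
Rscript inst/cli/lynchcea tree --strategy IHC_METH --status MSH2
```

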