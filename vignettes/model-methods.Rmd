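---
title: "Model methods: reflex Lynch-syndrome testing in endometrial cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its science: the model and
its assumptions, the parameters that matter, what the synthetic data
emulate, the numerical choices, and the design decisions taken where the
design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. Decision problem and structure

Women newly diagnosed with endometrial cancer (probands) may be tested for
Lynch syndrome by reflex tumour-based triage, direct referral, or not at
all. A diagnosis benefits the proband (colonoscopic surveillance) and her
relatives (cascade predictive testing, then surveillance for carriers).
The model couples:

1. a **decision tree** (module `tree`) that enumerates, per strategy and
   per true status (carrier of *MLH1*/*MSH2*/*MSH6*/*PMS2*, or sporadic),
   the exact probability of ending as confirmed LS, putative LS (PLS) or
   discharged, together with expected testing-phase costs; and
2. a **monthly-cycle Markov cohort model** (module `markov`) of lifetime
   colorectal-cancer outcomes, run per *profile* (carrier status and gene
   x surveillance x proband/relative x sex x start age) and mixed with the
   tree's probabilities (module `model`).

Cohorts run to age 100 with a one-month cycle. Transitions are assumed to
occur mid-cycle: rewards use the mean of adjacent state vectors (life-table
half-cycle correction) and are discounted at mid-cycle time at 3.5%/year.

## 2. Parameters that matter

* **Prevalence of LS in EC probands** — 3.9% at the base-case proband age
  of 60 (3.0% in the `low_prevalence` scenario). Prevalence falls with
  age; the packaged age curve is logit-linear with slope −0.07/year,
  anchored at 3.9% at 60 (a synthetic choice: only the anchor is printed
  evidence).
* **Gene mixture** — overall 16.9/24.6/47.7/10.8% for
  MLH1/MSH2/MSH6/PMS2, localised in age by Bayes' rule against relative
  EC-incidence curves; the packaged mixture table reproduces the published
  5-year knot table to printed precision (tested).
* **Tumour tests** — IHC sensitivity/specificity 94.4%/74.8% (failure
  3.7%); MSI 90.3%/77.1% (failure 1.9%). Staining pattern: dMLH1 in 89%
  of MLH1-carrier positives, 0.6% of other-carrier positives, 83% of
  sporadic positives.
* **Methylation triage** — after dMLH1 staining: sensitivity 95% (MLH1
  carriers continue), specificity 93.6%. The specificity is directional by
  true status: a *sporadic* dMLH1 tumour is truly methylated and is
  discharged with probability 0.936, while a *non-MLH1-carrier* dMLH1
  tumour is truly unmethylated and *continues* with probability 0.936.
  After MSI: MLH1 carriers continue with probability 0.95, 1/14 of
  non-MLH1 carriers and 67% of sporadics show methylation and are
  discharged.
* **Uptake** — 55% attend counselling, 10% of attendees decline testing;
  diagnostic germline testing has sensitivity 90%, specificity 100%;
  predictive testing of relatives is perfect, with Mendelian carrier
  probability ½.
* **Surveillance** — biennial colonoscopy, realised mean interval 2.1
  years at £583, active to age 75 (see §5). Incidence hazard ratio 0.38
  for carriers under surveillance (the unsurveilled incidence is the
  surveillance curve divided by the HR); stage at diagnosis shifts toward
  early stage under active surveillance. LS stage I–III CRC mortality HR
  0.66.
* **Utilities** — age/sex population norms, multiplied by 0.79 in stage IV
  CRC, zero when dead; no decrements for EC, testing or non-metastatic
  CRC.
* **Costs (2016/17 GBP)** — IHC £210, MSI £202, methylation £136,
  counselling offer £27, relative referral £36, pre-test counselling
  £347/£172 (proband/relative), post-test £133, diagnostic test £755,
  predictive test £166, colonoscopy £583, one-off CRC management cost by
  age and stage at incidence (no further CRC costs).

Analysis settings: 1000 probands and 6000 relatives; willingness to pay
£20 000/QALY; base-case relatives mixed over the packaged age
distribution, PSA/OWSA relatives at the single representative age 54.

## 3. Synthetic data: what it emulates, what it does not

No individual-level or registry data are shipped. The `synth` module
generates (and `scripts/make_fixtures.R` freezes as packaged CSVs):

* a Gompertz–Makeham **life table** (remaining female life expectancy at
  60 ≈ 25 years — computed in the test suite, not calibrated to any
  national table);
* **sporadic CRC incidence** (1.6/1000 at 60, doubling ~every 11 years;
  cumulative risk to 85 just over 9%, deliberately at/above registry
  levels — a calibration choice, see §6) and **stage-specific CRC
  mortality**;
* **gene- and age-specific LS CRC incidence under surveillance** (logistic
  ramps; MLH1 highest, then MSH2, MSH6, PMS2, emulating the prospective-
  registry risk ordering);
* **CRC management costs** by age and stage (stage IV dearest);
* utility **population norms**; the **EC age-at-diagnosis distribution**
  (unimodal, mode ≈ 62); the **relatives' age distribution** (truncated
  normal, mean ≈ 52); and study-level **diagnostic-accuracy tables** for
  the meta-analysis recovery tests.

A green test therefore establishes that the *machinery* is correct
(enumeration, cohort algebra, dominance logic, estimator recovery) and
that the *qualitative* published pattern (frontier membership, orderings,
age behaviour) emerges under a registry-shaped world — not that the
package reproduces the published absolute costs, QALYs or the £14 200/QALY
ICER, which depend on unpublished supplementary tables.

## 4. Numerical choices

* **Competing risks**: cause-specific annual rates are summed, the total
  converted by `1 − exp(−r·dt)`, and the probability apportioned to causes
  proportionally to rates — exact under constant hazards within a cycle.
* **Rate tables** are linearly interpolated in age and clamped at their
  ends.
* The cohort engine iterates the six-state occupancy directly (tested
  against explicit transition-matrix multiplication); mass conservation is
  enforced to 1e−9 per cycle.
* Colonoscopy is charged as a per-cycle equivalent (£583 / 2.1 years) on
  CRC-free alive occupancy while surveillance is active, making the
  undiscounted 21-year total exactly 10 colonoscopies.
* The bivariate meta-analysis maximises the exact marginal likelihood of
  the logit-normal approximation (L-BFGS-B on log-SD/atanh-correlation
  scale; 0.5 continuity correction applied to all cells of zero-cell
  studies). A binomial GLMM would be the natural extension.
* Frontier ties (identical cost and QALYs) keep the earlier-listed
  strategy; extended dominance removes interior strategies until
  consecutive frontier ICERs strictly increase. NMB ties in the CEAC split
  an iteration's probability equally.
* PSA draws derive per-iteration seeds deterministically from the master
  seed; invalid draws (none under the packaged families) are resampled
  with a 10x cap.

## 5. Design decisions on genuinely open points

* **Test failures** are referred onward (`failure_policy: refer`,
  configurable to `discharge`): failing a triage test is not evidence
  against LS, and referral is the clinically conservative reading.
* **Putative LS requires suggestive evidence.** Germline-tested carriers
  with a negative result are PLS everywhere (their family history is
  genuinely suggestive). Sporadic probands are PLS only when a *positive
  tumour test* was suggestive; under direct referral (or after a failed
  test) a negative germline test discharges them. Without this gate the
  direct-referral strategy would flood half of all sporadic probands into
  lifelong surveillance, contradicting every published ordering.
* **Surveillance of non-carriers** (sporadic PLS probands, unresolved
  relatives) leaves their underlying CRC incidence unchanged and acts only
  through the stage shift; the incidence hazard ratio is a
  carrier-surveillance estimate.
* **Surveillance window**: colonoscopy and its stage-shift benefit stop at
  age 75, mirroring guideline practice for surveillance programmes.
* **Adherence without a molecular diagnosis**: people managed on the PLS
  pathway enter surveillance with probability 0.5
  (`uptake.p_surveillance_unresolved`); confirmed carriers adhere fully.
  Long-term colonoscopy adherence in unconfirmed at-risk groups is known
  to be partial; the exact value is a synthetic placeholder.
* **EC mortality window**: the EC excess mortality rates (4.0/1000
  person-years for LS; 26.4–92.1 by age for sporadic, derived from 5-year
  survival) apply for the first five years after model entry; survivors
  are treated as cured.
* **PSA distribution defaults** (the original tables are unavailable):
  beta for probabilities (moment-matched, SE 10% of mean), gamma for unit
  costs (SE 20%), lognormal for hazard ratios, dirichlet for the gene
  mixture and stage splits (sampled jointly so vectors still sum to 1).
  All are configurable. Dirichlet specs are excluded from the one-way
  analysis (no univariate 95% limits).
* **Scenario values not printed in the source** (Arrigoni surveillance
  effect 0.82, Hampel methylation-after-MSI 0.76/0.0) are placeholders;
  the scenario machinery is the contribution, not the numbers.

## 6. Fixture calibration

The spec of the synthetic world was fixed once, in
`scripts/make_fixtures.R`: the natural-history levels above were chosen so
that the packaged base case displays the published qualitative behaviour —
IHC_METH the cheapest testing strategy and the only cost-effective one at
£20 000/QALY, IHC the most effective and most costly, the QALY ordering
IHC > MSI > IHC_METH > DIRECT > MSI_METH, a strictly decreasing per-age
INMB turning negative in the early 60s, and an age-threshold optimum
between 60 and 65 with positive value at 80. The load-bearing choices are
the sporadic incidence level (which powers the stage-shift value of
false-positive surveillance), the surveillance HR, the PLS adherence, and
the age-75 surveillance stop; they were set a priori from the constraints
above and frozen. The acceptance tests assert exactly these qualitative
facts and no more.

## 7. Known limitations

* Only colorectal cancer outcomes are modelled downstream; future EC in
  relatives, gynaecological surgery, aspirin chemoprevention and
  colonoscopy complications are out of scope by design.
* CRC states carry no progression between stage groups and no ongoing
  costs (one-off cost at incidence), per the source costing approach.
* The bivariate meta-analysis uses the normal approximation; exact
  binomial likelihoods would matter for very small studies.
* Absolute population totals are synthetic-world quantities; only
  increments and orderings carry meaning, and even those are conditional
  on the fixture world described above.
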