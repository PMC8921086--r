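---
title: "A decision-analytic model for M-staging imaging strategies in pancreatic cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A decision-analytic model for M-staging imaging strategies in pancreatic cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mstagecea)
```

## The clinical question

Half of pancreatic cancers are metastatic at diagnosis, and distant
metastasis — most often hepatic — contraindicates resection. Staging rests
on contrast-enhanced CT, whose sensitivity for liver metastases (roughly
70–76%) is well below that of contrast-enhanced liver MRI (90–97%). A
patient staged resectable on CT whose occult metastases would have been
seen on MRI undergoes a futile pancreatectomy: perioperative mortality risk
and surgical cost are incurred without survival benefit. `mstagecea`
implements a decision-analytic model that asks whether adding liver MRI to
the staging work-up (CE-MR/CT) is cost-effective relative to CT alone
(CE-CT) from a US healthcare perspective.

## Model structure

The model couples a diagnostic decision tree to a five-state Markov cohort
model with annual cycles over a 5-year horizon, starting at age 70.

**Decision tree.** The modeled cohort is patients classified *resectable*
on CE-CT. With probability `p_ct_tp` = 0.9225 that classification is
correct; the complementary `p_ct_fp` = 0.0775 carries occult metastases.
Under CE-CT every cohort member is operated. Under CE-MR/CT the added MRI
detects the occult metastases of CT false positives with probability
`p_mri_detect` (default 1; the literature reports 90–97% sensitivity, so
the parameter is exposed rather than hard-wired) and those patients are
reclassified to non-resectable palliative management, avoiding surgery.
Perioperative mortality (3.7%) applies once, at model entry, to operated
patients; the perioperative dead accrue the upfront diagnostic and surgical
cost but no utility. Patients classified non-resectable on CT itself are
identical under both strategies and cannot generate an incremental
difference, so they are excluded from the cohort; an MRI false-negative
rate among truly resectable patients is taken as zero (no published value
exists, and its effect would again be shared by both arms).

**Markov states.** `NONRES` (alive, non-resectable, palliative therapy),
`RES_NED` (alive, resected, no evidence of disease), `RES_LOC` (alive,
resected, R1 situation or local recurrence), `RES_MET` (alive, resected,
metastatic — either recurrence or metastases missed at staging), `DEAD`
(absorbing). Annual transition probabilities: 38%/yr metastasis occurrence
after resection, 50.74%/yr mortality with metastatic disease, 2.9%/yr
mortality without. Competing risks are composed death-first — the state's
death probability is applied and non-death transitions act on survivors —
which keeps rows stochastic for any valid inputs, including perturbed ones
in the sensitivity analyses.

**Rewards.** Each alive state carries an annual cost and a utility weight;
resected disease-free patients have first-year variants ($36,126 then
$1,126/yr follow-up; utilities below). Metastatic therapy costs $60,000/yr
in both the never-resected and post-resection metastatic states; the
R1/local-recurrence state costs $30,000/yr. Costs and QALYs are discounted
at 3%/yr; the upfront cost sits at time zero and is undiscounted.

## Structural choices and the structure search

The published description leaves several mechanics open. Rather than guess
silently, each open choice is an explicit flag (see `?structure_flags`),
and `structure_search()` enumerates all 96 combinations, scoring each by
its maximum relative error against the four published base-case outputs
(cost and effectiveness of both strategies). The package defaults are the
selected combination:

* **Reward accrual (`accrual = "start"`).** Rewards are valued on the
  cycle-*start* occupancy and discounted at the time of accrual
  (`1/(1+r)^(k-1)` for cycle *k*); the alternatives are end-of-cycle
  accrual and the half-cycle correction. Start-of-cycle accrual is what the
  published totals are consistent with — end-of-cycle accrual
  underestimates both cost and effectiveness by over 10% here because the
  heavy first-cycle mortality then erases the first year's rewards.
* **M0 post-surgery utilities (`utility_set = "low"`).** Two utility pairs
  for resected metastasis-free patients appear in the source literature:
  0.79/0.87 and 0.726/0.797 (first year / later years). Both ship; the
  lower pair is the default — it is the pair the published methods text
  states was used, and the search selects it independently.
* **R1 proportion (`r1_split_timing = "annual"`).** The "80% of
  resections are R1" input is not tied to a specific transition in the
  published description. Interpreted as an annual hazard
  (disease-free → R1/local at 80%/yr among survivors not progressing to
  metastasis) the base case is reproduced; the at-entry split (80% start in
  the R1 state) is retained as the alternative.
* **R1 state mortality and utility.** No mortality or utility is published
  for the R1/local-recurrence state. It uses the non-metastatic death
  probability (`r1_mortality = "m0"`, overridable with an explicit value)
  and the M0 post-surgery utility pair, and it can progress to metastasis
  at the same 38%/yr as the disease-free state.
* **Metastatic mortality onset (`m1_mortality_onset = "deferred"`).** The
  50.74%/yr metastatic mortality first applies in the second model year;
  cycle 1 has no metastatic deaths. This reads the annual figure as the
  mortality of prevalent metastatic disease rather than of the entry year,
  and it is the single largest contributor to matching the published
  totals after accrual timing ($5k+ of cost and most of the remaining QALY
  gap). With `"immediate"` the published cost level cannot be reached
  under any combination of the other flags.
* **Metastatic follow-up costs (`met_followup = TRUE`).** Resected
  patients with metastases pay the $1,126/yr post-surgery follow-up on top
  of metastatic therapy after their first year.
* **First-year reference (`first_year_reference = "global"`).** First-year
  cost/utility variants key on model cycle 1 (surgery happens at entry).
  The alternative keys on time since state entry, implemented through
  internal first-year phases of the R1/local and metastatic states; the
  phases share transition rows, so the public five-state matrix is exact.

Under these defaults the model yields $186,346 / 2.3203 QALYs for CE-CT
and $183,966 / 2.3358 QALYs for CE-MR/CT — within 0.9% and 0.017 QALYs of
the published $187,601 / 2.337 and $185,597 / 2.347. The residual misfit
is expected: the original model was built in a commercial tree package
whose exact accrual and tunnel mechanics are not published.

```{r structure-search, eval = FALSE}
ss <- structure_search()
head(ss$report)   # every combination, ranked by max relative error
ss$best           # the shipped defaults
```

## Base case and decision metrics

```{r basecase}
bc <- base_case()
bc
```

The comparison reports incremental cost, incremental QALYs, the ICER and
per-strategy net monetary benefit (NMB = WTP × QALYs − cost, WTP
$100,000/QALY). Because the dominant quadrant makes the ICER's sign
ambiguous as a decision rule, dominance and preference are decided on NMB.

## Sensitivity analyses

**Tornado (one-way).** Every operative input is varied ±25% around its
base value, clipped to its valid support, and the incremental NMB of
CE-MR/CT is recorded at both endpoints (`tornado()`). CT accuracy is
varied through the false-positive rate with `p_ct_tp` kept complementary —
+25% on a probability of 0.9225 would leave the unit interval, and
clipping it to 1 would merely rediscover the threshold result below.
`start_age` (not operative: the 2.9%/yr non-metastatic mortality stands in
for age-specific life tables, with age dependence deliberately out of
scope) and `horizon` (structural) are not varied. A number of inputs — the
M0-pathway costs and utilities, `p_r1`, `p_met_after_resection`,
`p_death_m0`, `cost_ct` — produce zero-width bars: both arms contain the
same absolute mass of resected metastasis-free patients
(`p_ct_tp × (1 − p_surgery_death)`), so those rewards cancel exactly in
the increment. The incremental NMB stays positive at every endpoint.

**Threshold.** `threshold_resectability()` bisects the NMB difference on
the CT correct-classification probability. At the defaults the crossover
is 98.95%: below it the averted futile surgeries outweigh the MRI cost and
CE-MR/CT is preferred; above it the MRI is pure cost (published value:
98.88%).

**PSA.** `run_psa()` draws all probabilities and utilities from Beta and
all costs from Gamma distributions, independently, moment-matched to the
base values as means. The published analysis states 30,000 iterations but no
distributions, so conventional CEA families apply with default standard
errors of 10% of the mean for probabilities/utilities (Beta SDs capped at
95% of the maximum compatible with the mean; degenerate at base values of
0 or 1, so `p_mri_detect = 1` stays fixed unless overridden) and 20% for
costs; every hyperparameter and each parameter's sampler can be overridden
in `psa_spec()`. With these defaults CE-MR/CT has the higher NMB in about
63% of iterations at WTP $100,000 and about 54% at WTP $0 — majorities,
as published, though the margins obviously depend on the assumed
distributions. Reproductions of the published PSA and tornado figures are
therefore qualitative (signs and orderings), not bit-level.

## The microsimulation oracle

`simulate_patients()` is an individual-level Monte Carlo simulator that
samples each patient's diagnostic branch, surgical outcome and annual
transitions from exactly the matrices the cohort engine uses, and accrues
rewards under the same accrual convention. Because the two share one
source of transition truth, disagreement isolates accumulation or
discounting bugs. The test suite checks agreement within Monte Carlo error
at 200,000 patients for the base case and for 20 random valid scenarios
spanning edge regions (perfect classifier, certain metastatic death, zero
costs and discount, all structural-flag combinations, horizons 1–8).
`generate_test_scenarios()` produces those scenarios.

What the synthetic scenarios do *not* emulate: correlated parameter
uncertainty, age-dependent background mortality, tumor-stage
stratification, and any within-year event timing. Passing tests therefore
establish internal consistency of the implementation under the stated
structure, not external validity of the published inputs.

## Numerical choices

* Row-stochasticity is asserted to 10⁻¹² when matrices are built;
  occupancy conservation to 10⁻⁹ per trace row.
* The TP/FP complement is enforced to 10⁻¹² at validation; perturbation
  and PSA re-couple `p_ct_fp = 1 − p_ct_tp` after drawing `p_ct_tp`.
* Bisection uses a default tolerance of 10⁻⁵ on the probability scale and
  reports an explicit no-crossover result when the bracket has no sign
  change (e.g. on [0.5, 0.9], where CE-MR/CT is preferred throughout).
* An ICER with zero QALY difference is `NA`, never an exception; decisions
  use NMB.
* PSA iterations at the published 30,000 complete in well under a minute;
  the test suite uses that size once and smaller sizes (300–4,000) where
  only reproducibility or calibration is at stake.

## Known limitations

* The structural flags are calibrated to four published aggregate outputs;
  distinct flag combinations can tie (for instance, the first-year
  reference is irrelevant under the at-entry R1 split with flat metastatic
  costs), so the selected combination is a minimal consistent
  reconstruction, not a unique identification.
* Background mortality is a constant 2.9%/yr rather than age-specific life
  tables; with a 5-year horizon from age 70 the distortion is small, but
  the model should not be extrapolated to long horizons.
* Costs are US dollars of the publication period with no inflation
  indexing, and tumor stage is not modeled.
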