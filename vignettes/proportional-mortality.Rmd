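---
title: "Stage-specific proportional mortality: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-specific proportional mortality: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(propmort)
library(dplyr)
```

## Why proportional mortality

Screening questions are usually asked of survival curves, but survival by
stage at diagnosis is confounded by lead-time bias: moving the diagnosis
date earlier lengthens survival mechanically. The endpoint analysed here —
the distribution of final causes of death among people diagnosed with
cancer — does not move when the diagnosis date moves. The price is that
proportional mortality says nothing about absolute risk or about life-years:
a higher proportion of deaths from one cause can reflect either more risk
of that cause or less risk of the alternatives. Everything in this package
should be read with that in mind.

A case is described by its *index cancer* (the first primary defining
cohort entry), AJCC stage I–IV or Unknown (brain/other nervous system,
myeloma, and leukemia are always Unknown because they lack AJCC 6th
edition staging), a 5-year age band at diagnosis within 50–84, sex,
race/ethnicity, diagnosis year, observed follow-up in months, vital status
at last contact, and — for deaths — a detailed cause-of-death code.
Younger cases are excluded by design: their low background mortality means
almost all of them would be censored. Deaths with unknown cause are
removed by `apply_eligibility()` (0.8% in the registry analysis this
package follows) and logged.

## Cause classification

A death is an **index-cancer death** if the certificate's cancer site
matches the index site group; site matching happens at the parent level,
so a lung-cancer death after an index "Lung, Small-Cell" cancer is an
index death. Any other cancer site is a **non-index-cancer death** with
that site as its detail. Same-site second primaries do not occur in the
source coding convention, so the match is unambiguous; the synthetic
generator enforces the same rule. Non-cancer causes are collapsed from the
26 standard registry causes into grouped reporting causes by
`group_noncancer()`: tuberculosis, syphilis and other infectious/parasitic
diseases merge into *Other Infectious Diseases* (septicemia stays
separate); hypertension without heart disease, atherosclerosis, aortic
aneurysm/dissection and other arterial disease merge into *Other
Circulatory Diseases* (heart disease and cerebrovascular disease stay
separate); accidents/adverse effects merge with homicide/legal
intervention (suicide stays separate); and seven rare or ill-defined
causes pool into *Other*.

Breast cancers are refined by hormone-receptor status — positive if either
ER or PR is positive, negative if both negative, unknown otherwise. The
three-way outcome is standard; the either-positive rule is the
conventional reading and is stated here because only the outcome labels,
not the rule, are fixed by the source analysis. Lung is split small-cell /
non-small-cell on ICD-O-3 morphology; the shipped small-cell set
(8041–8045) is a placeholder that users with real registry data should
replace via `subtype_rules()`.

## The allocation engine

Let a stratum be (site group × stage). For each stratum the engine
computes, from observed deaths only, (a) the cause distribution per
follow-up year (year *k* covers months 12(k−1) < m ≤ 12k, month 0 in year
1, mirroring the 0–12 / 13–24 reporting bins) and (b) the pooled
distribution over the tail window: deaths whose follow-up month exceeds
the maximum attainable month minus `tail_window_months` (default 48, "the
final four years"). Then:

* observed deaths → their classified cause, weight 1 (`observed`);
* lost to follow-up in year *t* → the year-*t* distribution
  (`imputed_lost`);
* alive at the administrative end → the tail distribution
  (`extrapolated_alive`).

Allocation runs at detail resolution (non-index sites, grouped non-cancer
causes), so the detailed tables marginalise from the same weights as the
major table. Fractional weights are the default because they are
deterministic and exact in expectation; `mode = "sampled"` draws one
seeded cause per case for sensitivity checks.

**Assumptions.** The imputation step assumes censoring is independent of
cause given the stratum and follow-up year. The extrapolation step further
assumes the cause mix is stable over the tail window and representative of
survivors' futures — defensible because the index-cancer death hazard
plateaus ("statistical cure") roughly 10 years after diagnosis, but still
an approximation when non-cancer hazards keep rising with attained age.
The parameter-recovery test (below) is run in a world where the
assumption holds exactly; the default demo world deliberately violates it
mildly, as real data do.

**Numerical choices.** The source analysis is silent on cells with no
observed deaths, so a configurable fallback chain handles them: loss
year → adjacent years pooled (t±1) → stratum pooled over all years → site
group pooled over stages → global. Every fallback is logged in the
result; an exhausted chain is an error naming the stratum, never a silent
zero. Two genuinely open readings are both implemented: the distribution
of "the corresponding year of follow-up" for lost cases defaults to the
literal loss-year distribution, with a forward-looking mixture (deaths in
years ≥ loss year) behind `lost_mode = "forward"`; and the tail window is
anchored to follow-up time, not calendar time. Percentages are computed
from unrounded counts and displayed with half-up rounding (base `round()`
is banker's and does not reproduce published tables); rounded row
percentages may not sum to 100.

## Stage-shift scenarios

`run_scenario()` computes, for each site group and source stage with *N*
allocated deaths (= cases, since everyone dies by observation or
extrapolation) and *D* index deaths, counterfactual index deaths
*N·Σ<sub>t</sub> w(s→t)·p<sub>index</sub>(g,t)* using the target stage's
index proportion from the same table, and reports the averted deaths
summed per type. Running the same shift on the pooled all-types row gives
a different answer (a Simpson-type effect); the per-type sum is the
published definition and the default scope (mutually exclusive parent
groups, never subtype rows; unknown-stage cases are never redistributed).
The percent reduction divides by total index deaths *including* unknown
stage — the denominator is not stated in the source analysis, but this
choice reproduces its printed 6%/12%/32% and is self-consistent with
per-type summation; a known-stage-only denominator is available. On
small synthetic tables a target cell can be empty; `on_empty_target =
"pooled_stages"` substitutes the site's known-stage pooled proportions
and records the substitution (the default remains an error).

## The synthetic world

`default_cohort_params()` states a seven-site world (breast, prostate,
lung, colon/rectum, pancreas, melanoma, other) at roughly 1/100 of the
registry scale (11,500 cases). Its choices, fixed once:

* **Stage mixture per site** follows the registry pattern (prostate
  almost never stage I under AJCC 6; melanoma mostly stage I; half of
  pancreas stage IV).
* **Index hazard** = stage gradient (yearly death probability 0.012 /
  0.016 / 0.055 / 0.17 for stages I–IV; Unknown behaves like stage III,
  as it does in the registry tables) × site severity (0.45 prostate … 5.0
  pancreas, capped at 0.6/yr), with a cure plateau at year 10 cutting the
  hazard by 80%.
* **Non-cancer hazards** rise multiplicatively per attained 5-year age
  band (slopes 1.1–1.6 by cause), capped at band 7 (~85+) so yearly
  probabilities stay valid and the late-follow-up world is
  quasi-stationary. Baselines are set so the typical attained band lands
  near registry-like rates (heart disease ~0.009/yr).
* **Censoring**: diagnosis years 2006–2010 with a fixed calendar end —
  per-case administrative maximum 179 months minus elapsed months since
  the first accrual year — plus yearly loss to follow-up (0.7%),
  sequenced death-first within each year.

Under these defaults the simulated cohort shows survivor fractions of
~57–61% (stages I–II), 33% (III), 8% (IV) against the registry's
60/60/32/9, and provenance shares at stages I–II of roughly 36% observed /
6% imputed / 58% extrapolated against the published 40/5/55. The cause
mix is qualitatively right (non-cancer dominates early stages, index
dominates stage IV) but not calibrated cell by cell — the generator
emulates structure, not rates (explicitly a non-goal). Features of real
data it does not attempt: calendar trends in treatment and coding,
cause-dependent loss to follow-up, same-site second primaries, and
misclassified death certificates. A green test against this world
therefore establishes the *pipeline's* correctness, not registry realism.

The latent truth (every case's eventual cause and death month, simulated
to a 120-year horizon with a forced terminal draw for the vanishing
remainder) is written to a separate side-channel file that the analysis
never reads; it exists purely so recovery tests can compare allocated
proportions with the truth.

## What the recovery test establishes

The acceptance-level recovery experiment uses a dedicated six-stratum
world (equal weights on breast I and II, colon/rectum II and IV, lung III,
other I; n = 20,000; loss 2%/yr; age-flat non-cancer hazards; fixed seed).
Two design points deserve explanation. First, age-flat hazards: tail
extrapolation is exactly calibrated only when the post-cure cause mix is
stationary; with an age slope the method is mildly biased by construction
— that bias belongs to the method, and testing the implementation against
it would conflate the two. Second, the comparison uses the estimator's
actual standard error. All survivors of a stratum share one estimated
tail distribution, so the Monte Carlo error of the allocated proportion
is dominated by the number of observed tail deaths, not the stratum size:

$$\mathrm{SE}^2 \approx p(1-p)\left(\tfrac{1}{n} +
\tfrac{f_{\text{alive}}^2}{n_{\text{tail}}} +
\tfrac{f_{\text{lost}}^2}{n_{\text{dead}}}\right).$$

With that SE, allocated proportions recover the latent truth within 3 SE
in every stratum and cause, and with censoring switched off allocation
equals classification exactly.

## Reference-table reproduction

The package ships transcriptions of the source analysis's two summary
tables, verified by row-sum identities (every characteristic's stage
columns sum to the same totals; per-type cause totals match the case
counts). One transcription finding: the published all-types rows are not
the sums of the per-type rows (differences up to ~3,000 at stage I),
consistent with the pooled stratum having been extrapolated directly —
the same Simpson-type effect noted above, visible inside the published
table itself. The fixture keeps both as printed; headline summaries use
the all-types rows, scenario arithmetic uses the per-type rows, which is
how `cmd_reproduce_paper()` recovers the published 33,958 (6%), 62,092
(12%) and 32% to rounding. The breast HR subtype rows likewise nest in
"Breast, All" only to ~1–2%, for the same reason.

## Known limitations

Proportional mortality cannot separate increased risk of one cause from
decreased risk of another, and none of the outputs are absolute risks;
standardized mortality ratios and competing-risks quantities are out of
scope, as are life-years and any model of screening sensitivity,
adherence, overdiagnosis, or lead-time-adjusted survival. Death
certificates misclassify causes, possibly differentially by stage, and the
pipeline inherits that. The extrapolation step is only as good as the
stationarity of the tail; cohorts with short follow-up relative to the
cure point should expect bias that no fallback chain can repair.
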