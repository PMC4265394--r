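---
title: "Methods: the prognostic model, its validation toolkit, and the synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the prognostic model, its validation toolkit, and the synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predictebc)
```

## The model

`predictebc` implements a multiplicative proportional-hazards prognostic
model for early breast cancer. A patient's annual breast-cancer hazard in
year $t$ is

$$ h_i(t) = h_0^{ER}(t)\; \mathrm{HR}_{node}^{c_{node}}\,
\mathrm{HR}_{size}^{c_{size}}\, \mathrm{HR}_{grade}^{c_{grade}}\,
\mathrm{HR}_{screen}^{[screen]}\; m_{HER2}(x_{HER2})\; m_{KI67}(x_{KI67})\;
\pi_{rx}, $$

where $h_0^{ER}(t)$ is the ER-stratum baseline annual hazard, the $c$'s are
category codes (nodes: 0, 1, 2–4, 5–9, 10+; size: <10, 10–19, 20–29, 30–49,
50+ mm; grade: low/intermediate/high coded 0/1/2), and $\pi_{rx}$ is the
product of the hazard multipliers of the adjuvant therapies received.
The per-unit hazard ratios are the published registry estimates (ER+:
1.75, 1.43, 2.33, screen 0.70; ER−: 1.55, 1.44, 1.50, screen 0.86).

Two model versions are exposed. **v2** uses the clinicopathological factors
plus HER2; **v3** additionally includes KI67 status (positive defined as
>10% of tumour cells staining), in ER-positive disease only — KI67 carries
no prognostic signal in the ER-negative subgroup, so v2 and v3 are
identical there. This identity is asserted in the test suite and holds to
machine precision.

### Mean-one marker renormalization

A binary marker with hazard ratio $\rho$ and positivity prevalence $p$ is
entered through two relative hazards solving

$$ h_{pos} = \rho\, h_{neg}, \qquad p\,h_{pos} + (1-p)\,h_{neg} = 1, $$

i.e. $h_{neg} = 1/(1-p+p\rho)$. The prevalence-weighted average relative
hazard is exactly 1, so adding the marker redistributes risk between
marker-positive and marker-negative patients without shifting the cohort
average — the existing baseline survivor functions remain valid. For KI67,
$\rho = 1.3$ (an external cohort estimate supplied as configuration) and
$p = 0.412$ give $h_{neg} = 0.89$, $h_{pos} = 1.16$ after rounding. The
prevalence is not printed alongside the published relative hazards; 0.412
is the value implied by the two constraints and ships as the documented
default. The HER2 term uses the same construction; its hazard ratio (1.8)
and prevalence (0.089) are placeholders standing in for external estimates
that are configuration inputs, not claims.

Mean imputation interacts cleanly with this construction: an imputed
(fractional) status $x \in [0,1]$ enters as the prevalence weight
$(1-x)h_{neg} + x\,h_{pos}$, which equals 1 exactly at $x = p$. Fractional
grade or node codes produced by mean imputation enter as fractional
exponents.

### Competing risks on an annual grid

Other-cause mortality comes from a life table indexed by attained age.
Within each year, with cause-specific hazards $h_b$ and $h_o$, the
probability of dying is $S(t)\,(1-e^{-(h_b+h_o)})$ and is split between
causes proportionally to $h_b : h_o$ — the exact integral of a
piecewise-constant competing-risks model, so
$S + \mathrm{CI}_{bc} + \mathrm{CI}_{oc} = 1$ holds identically (tested to
$10^{-9}$). The annual grid matches the life-table structure and keeps
every quantity closed-form testable; the cost is that within-year covariate
changes (none exist in this model) cannot be represented.

Treatment benefit for an option is the overall survival (breast-cancer
survival × other-cause survival) with that option's hazard multiplier
applied to the breast-cancer hazard, minus the untreated curve, at 5 and
10 years; combined therapy multiplies the endocrine and chemotherapy
multipliers (0.70 and 0.78 by default — documented placeholders
approximating overview relative risk reductions, configurable).

Age enters only through the other-cause life table. The published per-unit
hazard ratio tables list no age term for the breast-cancer hazard, so none
is applied; an optional `hr_age_per_decade` configuration hook (centred at
age 50) allows one without code change.

### What is configuration, not code

The deployed baseline survivor functions behind the public tool are not
reproduced here. The shipped baseline annual hazards are **synthetic
plausible values**: ER+ rising to a broad mid-decade peak (10-year baseline
cumulative hazard ≈ 0.035), ER− peaked early (≈ 0.115), chosen so that a
cohort with the default covariate mix reproduces realistic 10-year
breast-cancer mortality (≈ 17% in ER+, ≈ 31% in ER−). Any analysis
that needs the deployed coefficients should supply them via
`read_model_config()`.

## Cohort handling

The staging exclusion removes node-negative patients with fewer than four
nodes sampled, for whom node negativity is unreliable; the boundary case
(exactly four sampled) is retained, the filter is idempotent, and records
with missing staging fields are kept — the exclusion targets inadequately
staged node-negative cases only. Missing node counts are mean-imputed on
the category-code scale (a design choice: cohorts report "missing" node
status as an analysis category, implying such records stay in).

Mean imputation uses the cohort's own observed means (recorded in the
imputation log) rather than external reference values; this is the simplest
reading of replacing a missing value "by the mean for that variable", and
the log makes the choice auditable. Binary markers imputed this way yield
the observed positivity proportion as a fractional status. Missing
detection mode multiplies the hazard by 1 (neither screening benefit nor
penalty). Pre-imputation missingness is kept in `*_missing` flags so
calibration tables can still show "Missing" strata.

## Validation metrics

* **Endpoint.** Ten-year breast-cancer-specific mortality. Other-cause
  deaths before the horizon are non-events; patients censored before the
  horizon are excluded from discrimination (the `exclude` censoring
  policy — the structure of the published analysis does not state its
  rule, so the policy is explicit, recorded in the report, and isolated
  behind `auc_statuses()` where an IPCW alternative could be added).
* **Calibration.** Expected deaths are sums of predicted 10-year cumulative
  breast-cancer mortality; observed counts carry exact Poisson 95%
  intervals (the standard choice for O/E death counts). Expected totals are
  additive over any partition, which the tests exploit.
* **Goodness of fit.** $\chi^2 = \sum (O-E)^2/E$ over quantile bins of
  predicted mortality. The default is quintiles judged against 5 degrees
  of freedom, matching the convention of quoting quintile calibration
  "(5 d.f.)"; `k` and `df` are configurable since $k-1$ or $k-2$ are also
  conventional, and the report always states the df used. Quantile binning
  breaks ties by a stable sort on (predicted value, id) so bins are
  reproducible.
* **Discrimination.** The AUC is the Mann–Whitney kernel mean (ties count
  one half), computed via midranks, with the DeLong placement-value
  variance. v2 and v3 are compared by DeLong's test for correlated AUCs:
  the variance of the AUC difference uses the covariance of the paired
  placement values. A zero-variance difference (e.g. identical scores)
  returns $p = 1$ with a degeneracy flag rather than failing. The
  implementation is cross-checked in the tests against exhaustive pair
  enumeration, against an independent ROC package, and against a
  stratified paired bootstrap.

## The synthetic-cohort generator

The generator emulates the structure of a 1990s UK hospital validation
series: 73.8% ER-positive; age, size, node and grade category frequencies
and per-variable missingness read off the ER-positive stratum of such a
series (reused for ER-negative patients — a convenience, not a claim);
HER2 positivity 8.9% with 31.8% missing. Where the series reports nothing,
values were fixed once at what is clinically plausible for the period and
are not meant to be revisited: 20% screen-detected (the national programme
was young), therapy dominated by endocrine treatment in ER-positive and by
first-generation chemotherapy in ER-negative disease, KI67 missingness set
equal to the HER2 rate (flagged assumption), and random censoring off by
default (registry-style complete follow-up to the 10-year administrative
horizon).

Covariates are drawn from the marginals independently (the generator does
not reproduce real-world correlations such as size–nodes association);
continuous size is uniform within its sampled bin. Outcomes are simulated
from the **true** covariate values before missingness is masked — matching
the real-world process in which biology acts on the tumour, not on the
case-report form — by inverse-transform sampling from each patient's
piecewise-exponential breast-cancer hazard and a life-table other-cause
hazard; the observed record is the earliest of the two death times and
censoring. Passing tests on these cohorts therefore show internal
consistency of engine and generator under ideal model specification; they
do not show calibration or discrimination on real data, where correlations,
measurement error and non-proportional hazards exist.

`recovery_experiment()` closes the loop: replicate cohorts are refitted
with cause-specific Cox regressions (`survival::coxph`) per ER stratum
using the engine's category codes, and the estimated log hazard ratios are
compared with the generator's truth. With 20 replicates of n = 5,000 the
Monte-Carlo SE of each mean estimate is about 0.01 on the log-hazard scale.
A caution about reading such experiments: judging eight coefficients
simultaneously against ±2 Monte-Carlo SEs gives each a ~5% chance of a
spurious miss, so about a third of seed choices will flag some coefficient
even when the estimator is unbiased — a single out-of-band term at one
seed is expected behaviour, not evidence of generator/engine inconsistency.
Therapy indicators that are rare in a stratum (endocrine therapy in
ER-negative disease, ~2% plus combined therapy) do carry visible
finite-sample Cox bias at ~20 treated events per replicate and are judged
only loosely in the tests.

## Problem sizes and numerical choices

The test suite exercises the oracle equivalences on 1,000 random ROC
instances (n ≤ 200 each, exhaustive pair enumeration), bootstrap
cross-checks with 10,000 stratified resamples, parameter recovery on 20
replicates of n = 5,000, calibration self-consistency at n = 10,000, and
discrimination-gain replications at n = 5,000 — sizes at which the
Monte-Carlo error of each summary is small relative to its assertion
tolerance while the whole suite remains quick to run.

Two honest findings from those experiments are worth recording. First,
calibration self-consistency: with generator = prediction configuration
the expected-to-observed ratio converges to ~0.98 rather than 1.00 when
the default missingness is on, because mean imputation of grade enters a
convex function (hazard-ratio powers) — Jensen's inequality makes imputed
predictions slightly under-estimate the cohort hazard. This is a real
property of mean imputation that the package makes visible, and it stays
comfortably inside the ±5% consistency band. Second, discrimination gain:
with a true KI67 hazard ratio of 1.3 at prevalence 0.41 on top of the full
clinicopathological score, the true AUC improvement under these generator
conditions is ≈ 0.0015, so a single cohort of n = 5,000 (≈ 630 ER-positive
events) rejects the no-improvement null in only a minority of replicates.
The mean improvement is reliably positive across replicates, but
per-cohort significance at this effect size would need several-fold more
events; published single-cohort significance for such a marker is
consistent with a larger realized effect in that cohort than the external
hazard ratio used here.

## Known limitations

* Baseline hazards, HER2 parameters and treatment multipliers are
  documented placeholders; results with the defaults characterize the
  machinery, not the deployed clinical tool.
* Covariate independence in the generator understates real-data
  confounding; parameter recovery under correlated covariates is untested.
* The censoring policy for discrimination excludes early-censored patients
  rather than reweighting them (IPCW is left as an extension point).
* Multiple imputation and missingness-mechanism modelling are out of
  scope; only cohort-mean imputation is provided.
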