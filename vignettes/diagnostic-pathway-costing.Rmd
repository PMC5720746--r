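---
title: "Costing a diagnostic pathway: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Costing a diagnostic pathway: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dxpath)
```

## The problem

When a patient presents with suspected lung cancer, the diagnostic
work-up runs through imaging (chest X-ray, CT, PET/CT, brain MRI, bone
and ventilation/perfusion scans), tissue acquisition (bronchoscopy,
EUS/EBUS, mediastinoscopy, CT-guided biopsy, thoracocentesis),
functional assessment of operability (lung function, VO2 max, ECG) and,
increasingly, molecular profiling (KRAS/EGFR, ALK), ending in a TNM
stage or the exclusion of malignancy. Hospitals differ in how often they
use each modality, partly for structural reasons (on-site PET/CT
availability, referral patterns) and partly through uneven guideline
adherence. dxpath quantifies that variation and its budget consequence
from patient-level usage records.

## The state-transition cost model

The pathway is modelled as four ordered non-terminal stages — imaging →
invasive → functional → molecular — each holding its member modalities,
with start state "suspicion of lung cancer" and terminal states "TNM
stage" / "no malignancy". The only quantities the calibration data
provide are *marginal* per-modality usage probabilities $p_i$ and unit
costs $c_i$; no transition sequence or within-patient test correlation
is identified. Under marginal parameterization the expected per-patient
cost of any traversal order collapses to the linear form

$$E[C] \;=\; \sum_i p_i \, c_i ,$$

which is what `expected_cost()` evaluates. The stage structure is kept
in the model object for reporting and future sequencing logic rather
than because it changes $E[C]$. Two consequences worth keeping in mind:
the model is exactly linear in every $p_i$ and $c_i$ (tested as an
invariant), and the cohort mean of the per-patient observed costs equals
$E[C]$ evaluated at the empirical rates to floating-point precision —
`observed_cost()` and `expected_cost()` are two views of the same
estimator.

### Rate estimation

Usage of a modality is Bernoulli per patient, so a cohort count $k$ out
of $n$ evaluable patients gives a conjugate beta posterior
$\mathrm{beta}(k + a,\; n - k + b)$. The default prior is Jeffreys
$a = b = 1/2$: an objective default for binomial proportions that keeps
the posterior proper at $k = 0$ or $k = n$; nothing in the calibration
data motivates a more informative choice. The reported point estimate is
the raw rate $k/n$ (not the posterior mean), so printed tables match
simple tabulation; the posterior feeds the credible intervals and the
PSA. Intervals are equal-tailed 95% (`qbeta(0.025)`, `qbeta(0.975)`)
rather than highest-density: equal tails are reproducible without
optimization, at the cost of a lower bound strictly above zero for
never-used modalities — that bound is prior mass, and is documented
rather than clamped.

**Evaluable denominators.** Usage flags may be missing for individual
patients (unreadable files, external work-ups). A missing flag is "not
evaluable": the patient leaves that modality's denominator instead of
being imputed as unused. In the default calibration the two cohorts of
214 and 162 patients yield evaluable denominators of 212 and 152 — the
only reconstruction under which the tabulated counts reproduce the
tabulated percentages (e.g. 186/212 = 87.7%).

### Between-hospital testing

`chi2_independence()` is Pearson's chi-squared on the 2×2 used/not-used
× hospital table, one degree of freedom, delegated to
`stats::chisq.test()`. The Yates continuity correction is **off** by
default (a flag enables it): the corrected and uncorrected conventions
disagree at these sample sizes, and the transparent
$\sum (O-E)^2/E$ statistic is the one the test suite can verify against
an exhaustive brute-force oracle (all 2×2 tables with row margins up to
30). Tables with a zero margin are rejected with an error naming the
degenerate margin rather than returning NaN. No multiple-testing
correction is applied across the 19 modalities; the table reports raw
p-values with a 0.05 significance flag.

### Costing and currency

Unit costs come from the built-in 2014 NZa tariff table (17 priced
procedures, euros). Two bases are available: the NZa `tariff` column
(default, the basis of the headline budget-impact figures) and the
`hospital_cost` column. Money is handled in exact integer cents
internally — tariffs are converted once via `round(x * 100)` and summed
as integers in the patient-level path — and reported in euros at two
decimals, so long sums cannot drift.

**Tariff mapping.** The modality registry (19 entries) and the tariff
table (17 rows) do not align one-to-one. The default mapping prices each
unpriced modality under its closest procedure class: broad lung function
under "flow volume + diffusion" (EUR 67.60), post-biopsy chest X-ray
under the plain X-thorax tariff (EUR 43.66), X-ray guidance during
bronchoscopy under the X-ray guidance tariff, and bone scintigraphy —
the one genuinely unpriced scan — under the ventilation/perfusion-scan
tariff (EUR 225.78) as the nearest nuclear-medicine class. Every mapping
is inspectable (`default_tariff_mapping()`); dropping an entry excludes
the modality from costing with a logged message instead of failing.
Under this mapping the reconstructed per-patient budget impacts are
EUR 2141.72 (teaching) and EUR 2393.56 (academic), 2–4% below the
published model's EUR 2191 / EUR 2496; the residual is attributable to
flows the published aggregation does not itemize (repeat tests, a
twentieth unpriced modality), and no mapping choice here is tuned to
close it.

### Probabilistic sensitivity analysis

`run_psa()` propagates rate uncertainty only: each replicate redraws
every $p_i$ from its beta posterior, independently across modalities and
hospitals (matching the independent-binomial sampling model), and
re-evaluates $E[C]$. Tariffs are treated as fixed administered prices,
not sampled. Because $E[C]$ is linear in $p$, the PSA mean converges to
the plug-in cost at the posterior-mean rates — a closed-form target the
tests assert at 10^4 draws within three Monte-Carlo standard errors.
One integer seed drives the run; each (modality, hospital) pair receives
a deterministically derived substream so results are independent of
evaluation order and byte-reproducible.

## The adherence audit

An `adherence_rule()` states when a modality is indicated, as a
predicate over stage and histology, plus the indicated casemix fraction.
The guideline-expected count for a cohort of size $n$ is
$\lfloor f \cdot n + 0.5 \rfloor$ — round half-up, the convention under
which a 16.7% stage-III casemix of 162 patients expects 27 brain MRIs
and a 20% casemix of 214 expects 43. The deviation
(observed − expected) is costed at the modality's unit cost; direction
is `over`, `under` or `concordant`. The fraction can be supplied
directly (as published audits do) or computed from the cohort's own
casemix; the mode is recorded per report row. Patients with unknown
stage are excluded from stage-conditional predicates — they neither
satisfy nor violate the indication. The default rule set contains the
single quantitative rule available: brain MRI indicated iff stage III,
with fixed casemix fractions 0.20 (teaching) and 0.167 (academic);
anything further is user configuration, because encoding the full Dutch
lung-cancer guideline is out of scope.

## The synthetic-cohort generator

`generate_cohort()` emulates the structure the analysis assumes: per
hospital, sex ~ Bernoulli(male fraction), age ~ Normal(mean, sd)
truncated to (18, 100] by inverse-CDF (an adult oncology cohort; the
published dispersion ≈ 10.3 years is treated as a standard deviation —
it is implausible as a standard error at n ≈ 200), histology and stage
categorical, and each usage flag an independent Bernoulli at the
configured rate. The defaults are the study conditions: n = 214 / 162,
ages 66.95 (10.335) / 65.77 (10.180), male fractions 63.6% / 59.9%,
the observed histology casemix, stage-III fractions 0.20 / 0.167, and
the tabulated usage rates. The calibration gives no stage distribution
beyond stage III, so the remaining mass is spread uniformly over stages
I, II and IV — a flagged convention, not an empirical claim.

What the generator deliberately does **not** model: correlation between
usage flags within a patient (only marginal rates are identified),
referral sequences, repeat tests, false-positive work-ups of patients
who turn out not to have cancer, and missing usage flags. Passing tests
therefore demonstrate that the pipeline recovers the parameters of this
independence structure — they do not validate the model against the
dependence patterns of real diagnostic data.

Reproducibility: one integer seed, per-hospital sub-seeds drawn
deterministically from it, and the global RNG state restored on exit;
identical configs give byte-identical cohort CSVs.

## Numerical choices and degenerate inputs

- Simplex validation tolerance 1e-9 on histology and stage fractions;
  YAML serialization should use enough digits (the reader does not
  renormalize silently).
- Money: integer cents internally, euros at two decimals on output.
- Expected counts: round half-up (`floor(x + 0.5)`), not banker's
  rounding.
- Empty cohorts, zero-margin 2×2 tables, rules on unregistered
  modalities, unmapped modalities without an exclusion policy, and
  nonpositive PSA draws all fail fast with named errors rather than
  propagating NaN.
- Age truncation bounds (18, 100]; at ~4.7 sd from the mean the
  truncation shifts moments negligibly.

## Problem sizes used by the test suite

The suite exercises the generator's law-of-large-numbers properties at
n = 10^5 per hospital (every usage rate within 3-sigma binomial bounds),
the PSA against its closed-form mean at 10^4 draws, and the chi-squared
engine against exhaustive enumeration of 2×2 tables with row margins up
to 30 (~240,000 tables). These sizes give the properties sharp
deterministic verdicts under the suite's fixed seeds while the whole
suite stays in the tens of seconds.

## Known limitations

The model prices a single diagnostic episode: no discounting, no
treatment costs, no time horizon beyond diagnosis, no national
extrapolation. The headline budget impacts inherit the 2–4% aggregation
gap discussed above. The audit encodes one quantitative rule by default.
Rates and tests treat patients as exchangeable within hospital — casemix
adjustment beyond the stage/histology predicates is out of scope.
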