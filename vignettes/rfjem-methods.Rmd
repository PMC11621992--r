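---
title: "Methods: JEM linkage, exposure metrics and exact conditional logistic regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: JEM linkage, exposure metrics and exact conditional logistic regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfjem)
```

## The problem

Occupational RF-EMF epidemiology rarely has personal dosimetry. What it
has is (i) lifetime occupational histories coded to 4-digit ISCO88, and
(ii) a job-exposure matrix (JEM) assigning each code an exposure
*intensity* and a *prevalence* of exposure. `rfjem` turns these into
per-participant exposure metrics and matched-set odds ratios. This
vignette records the model, the conventions, and the choices made where
more than one defensible convention exists.

## Intensity scale

Intensities are dimensionless ICNIRP squared ratios: for a source with
arithmetic-mean field level $\bar G_s(f)$ (E in V/m or H in A/m) and
frequency-specific occupational reference level $G_{RL}(f)$,

$$ \mathrm{ratio} = \left( \bar G_s(f) / G_{RL}(f) \right)^2 , $$

proportional to the specific absorption rate above 100 kHz. Squaring and
normalising by the reference level makes sources at very different
frequencies commensurable; `icnirp_ratio()` exposes the primitive so a
JEM can be assembled from source measurements. The package treats the JEM
as already aggregated to one time-weighted-average intensity per
(code, field): upstream source-combination weights (operating distance,
proportion of shift, head-level upweighting, expert confidence) belong to
JEM construction, not linkage, and are out of scope here. E and H fields
are independent in near-field conditions and are carried separately
through every stage; intermediate and high RF bands are assumed
pre-summed into a single intensity per code.

## Attribution methods

Per job spell, Method 1 applies the JEM intensity to every exposed
occupation; Method 2 additionally requires the occupation's exposure
prevalence to reach the median prevalence among exposed occupations
(`median_prevalence_threshold()`); Method 3 requires the participant to
have reported RF-EMF source use in that job. Two conventions had to be
fixed:

* *Median:* the standard sample median — mean of the two middle order
  statistics for an even count — over entries with prevalence > 0 only.
* *Threshold comparison:* at-or-above (≥) keeps an occupation exposed.
  "Above" was equally defensible; ≥ was chosen once and is asserted in
  the tests (a prevalence exactly at the threshold stays exposed).
* Method-3 gating is per spell, not per participant: only the jobs in
  which source use was reported contribute.

Occupation codes absent from the JEM, entries with prevalence 0, and
nonstandard spells (housewife/husband, pensioner, training,
imprisonment) contribute zero intensity.

## Year conventions and exposure metrics

All dates are calendar years; sub-year durations are not modelled (job
start/end are only known to the year). A spell covers years
start..end inclusive. For reference year $R$:

* lag $L$ sums yearly intensity over years $\le R - L$;
* window $(a, b)$ sums over $R - b \le y \le R - a$.

These conventions make the partition
$\mathrm{cum}(\mathrm{lag}\,1) = \mathrm{win}(1,4) + \mathrm{win}(5,9) +
\mathrm{cum}(\mathrm{lag}\,10)$ exact, which the suite asserts for every
participant, method and field. Years covered by $k$ concurrent spells
take the arithmetic mean of the $k$ spell intensities, unexposed spells
entering as zeros — a deliberate reading of "averaged over overlapping
years" that keeps a concurrent unexposed job dilutive.

TWA divides cumulative exposure by *years worked* in the same period.
"Worked" counts calendar years covered by any spell, including retained
nonstandard spells: they occupy calendar time in the history and enter
as unexposed periods, and a single denominator convention keeps
TWA × years = cumulative exact. (Dividing by exposed years only was the
alternative reading; it inflates TWA for intermittently exposed careers
and breaks that identity, so it was not adopted.) A participant with no
worked years in a period has TWA 0 by definition; positive exposure with
zero worked years is a contract violation, not a silent 0/0.

Reference dates: diagnosis year for cases; interview year minus the
cases' median diagnosis-to-interview gap (rounded half-up to a whole
year) for controls. The gap is computed per tumour type, pooled across
countries — per-country gaps are not described for the design this
emulates, and pooling is the smaller-variance choice.

## Exclusions

Five ordered criteria, each participant counted once under the first
matching criterion: (1) uncertain/unknown source information or no
occupational history; (2) missing education; (3) chronological issues
(unknown years, end before start); (4) nonstandard-only histories;
(5) any unknown occupation code. The order follows the narrative order
of the study design the package emulates; the ledger makes it auditable
and asserts conservation (initial = final + sum excluded) on every run.
Nonstandard spells alongside real jobs are retained as unexposed
periods. Exclusion is idempotent, which the suite checks.

## Categorization

Cut-points are the 50th/75th/90th percentiles of the metric among
*exposed controls* (cases never influence cut-points; the never-exposed
form the reference group, so including their zeros would only shift all
cut-points downward — a robustness variant is available via
`include_zeros`). Quantiles use linear interpolation between order
statistics (`stats::quantile` type 7), the common default; the
categories are half-open intervals with ties at a cut-point falling in
the lower category. After any sensitivity filter that changes the
control set — including 99th-percentile trimming — cut-points are
recomputed from the controls actually in the run.

## Exact conditional likelihood

With stratum $k$ containing $d_k$ cases among $n_k$ subjects and linear
predictors $\eta_i = x_i^\top\beta$, the conditional likelihood of the
stratum is

$$ \frac{\exp\left(\sum_{i \in \mathrm{cases}} \eta_i\right)}
        {\sum_{|S| = d_k} \exp\left(\sum_{i \in S} \eta_i\right)} , $$

free of stratum intercepts. The denominator is the elementary symmetric
function of order $d_k$ in $w_i = e^{\eta_i}$, evaluated by the
recursion $f(j, r) = f(j{-}1, r) + w_j f(j{-}1, r{-}1)$ with first and
second derivatives propagated through the same recursion (C++,
`src/cond_loglik.cpp`). Numerical choices:

* $\eta$ is centred within each stratum (the likelihood is invariant to
  a constant shift — tested numerically), and the $f/h/q$ arrays are
  rescaled in common when they exceed 1e250, so no log-space arithmetic
  is needed;
* Newton–Raphson from $\beta = 0$ with step halving; convergence when
  the relative log-likelihood change is below 1e-8 *and* the largest
  score component is below 1e-6, capped at 50 iterations;
* covariance is the inverse observed information at the optimum;
* strata with no cases or no controls are non-informative: dropped and
  counted, never an error;
* monotone likelihood (separation) is detected by coefficient divergence
  (|β| > 15) or a non-invertible information matrix and reported as a
  non-converged fit; `odds_ratios()` refuses such fits rather than
  printing an infinite OR. The exact likelihood was preferred over the
  Breslow approximation because pooled matching can put many cases in
  one stratum, where the approximation is poorest; Breslow remains
  available (`likelihood = "breslow"`).

The recursion is verified against exhaustive subset enumeration for
strata up to size 12 and against an independent established
implementation (`survival::clogit`, method "exact") to four decimals;
the all-equal-η stratum collapses to $1/\binom{n}{d}$ and the matched
pair to $\beta - \log(1 + e^\beta)$ in closed form.

The trend test replaces the four category indicators with a single
ordinal score 0–4 (unexposed through highest; the scoring over all five
levels was chosen since the reference group is part of the gradient) and
reports the Wald p-value of its coefficient; a score constant within all
informative strata is not estimable and is reported as p = 1 by
symmetry.

Education enters all pipeline fits as two indicators against a
high-school-or-less reference; 95% CIs use the normal 1.96 quantile with
no small-sample correction.

## The synthetic generator

`generate_jem()`/`generate_cohort()` emulate the *structure* of a
multicentre occupational brain-tumour case-control study: 468 ISCO88
codes with 62% exposed; job-level exposure prevalence Beta(0.8, 12)
(median ≈ 5%, matching the "low prevalence, high skew" regime);
lognormal intensities with E/H latent-normal correlation 0.93 (Spearman
≈ 0.9); careers of 27.6 ± 12 years over ~3 jobs placed on the calendar
with occasional gaps and overlaps; interviews 2000–2004; marginal age /
sex / region / education distributions taken from the reference control
margins. Source-report flags are noisy observations of true job-level
exposure (default sensitivity 0.9, specificity 0.99), which
operationalizes recall error and drives the M1 > M2 > M3 prevalence
ordering. Disease status is assigned by a stratified logistic model on
the category of a configurable target metric with configurable log odds
ratios — the same family the analysis fits, making parameter recovery
well-posed. Both tumour types share the configured effect; the
analysis-side grid fits each against all controls.

What the generator does **not** emulate: real national occupation
distributions, within-code intensity variability (each code has one true
intensity), hours-per-week weighting, sub-year job durations, and
confounding between exposure and the matching factors beyond the random
stratum intercepts. Passing tests therefore demonstrate correctness of
the linkage, accounting and estimation machinery under a realistic
sampling structure — not that any particular real-data association is
reproduced.

Exclusion-triggering defects (uncertain sources, missing education,
incoherent years, nonstandard-only histories, unknown codes) are
injected at configurable per-criterion rates into disjoint participant
subsets, so ledger counts are interpretable.

## Problem sizes used in the checks

The simulation-based checks use sizes chosen to make Monte-Carlo error
small relative to the tolerances asserted: odds-ratio recovery uses 500
cohorts of n ≈ 2000 with a true OR of 1.5 in the top category (mean
log-OR within 3 Monte-Carlo standard errors of log 1.5; CI coverage in
[0.93, 0.97]); trend-test size uses 1000 null cohorts of n = 800
(rejection at α = 0.05 within [0.03, 0.07]); the oracle comparison uses
200 random strata of size ≤ 12; the exposure-algebra identities use a
1000-participant cohort across all methods and fields. The acceptance
script repeats these at 300/600 replicates and reports the measured
values. The full analysis grid (2 outcomes × 2 fields × 3 methods × 2
metrics × 5 labels = 120 cells × 4 category ORs) is asserted on a
6000-participant cohort, the size at which every cell is estimable.

## Known limitations

* Exposure is resolved to whole calendar years; spells shorter than a
  year and within-year overlap structure are invisible.
* The JEM is a point intensity per (code, field); within-occupation
  variability and peak exposures are not modelled.
* Wald CIs and trend tests rely on asymptotic normality; in very sparse
  categories the monotone-likelihood guard will flag the cell rather
  than estimate it.
* The 99th-percentile trim uses the exposed-control distribution, for
  consistency with the cut-point logic; trimming on all participants is
  a defensible alternative not implemented.
* Extended lags (15/20/25) and windows (10–14/15–19/20–24) are supported
  but off by default, mirroring their sensitivity-analysis role.
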