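# rfjem

Occupational exposure to radiofrequency electromagnetic fields (RF-EMF,
100 kHz–300 GHz) is usually assessed in case-control studies by linking a
**job-exposure matrix (JEM)** — a table assigning an exposure intensity and
an exposure prevalence to each 4-digit ISCO88 occupation code — to each
participant's lifetime occupational history, and then relating the
resulting exposure metrics to disease risk with matched-set regression.
`rfjem` implements that full pipeline for brain-tumour (glioma /
meningioma) case-control data, together with a synthetic-data generator
with known effect sizes so every stage is testable without access to any
restricted study data.

It is aimed at occupational epidemiologists and biostatisticians who need
a reproducible, auditable implementation of:

* **JEM linkage under three attribution methods.**
  M1 applies JEM intensities to every exposed job; M2 zeroes jobs whose
  exposure prevalence falls below the median prevalence among exposed
  occupations (fewer false positives); M3 keeps only jobs in which the
  participant reported using an RF-EMF source. Intensities are
  dimensionless *ICNIRP squared ratios*,
  (Ḡ_s(f) / G_RL(f))², the squared ratio of the arithmetic-mean field
  level of a source to its frequency-specific occupational reference
  level — proportional to the specific absorption rate above 100 kHz, and
  therefore comparable across frequencies. E (V/m) and H (A/m) fields are
  carried independently end to end.

* **Cumulative and time-weighted-average (TWA) exposure** over lags
  (1/5/10, optionally 15/20/25 years) and time windows (1–4/5–9,
  optionally 10–14/15–19/20–24 years) before a reference date (diagnosis
  year for cases; for controls, interview year minus the cases' median
  diagnosis-to-interview gap). A spell covers calendar years start..end
  inclusive; lag L covers years ≤ ref − L and window (a, b) covers
  ref − b .. ref − a, so cumulative(lag 1) = window(1–4) + window(5–9) +
  cumulative(lag 10) exactly. Concurrent spells are averaged.
  TWA = cumulative / years worked in the same period.

* **Control-based categorization.** Categories are anchored at the 50th,
  75th and 90th percentiles of the exposure distribution among *exposed
  controls*; the never-exposed form the reference group (switchable to the
  low-exposed group for sensitivity analysis).

* **Stratified conditional logistic regression by the exact conditional
  likelihood.** Strata are the matching factors (5-year age group × sex ×
  country/region); models adjust for education. The matched-set
  denominator — an elementary symmetric function over all case-sized
  subsets — is evaluated by the stable recursion
  `f(j, r) = f(j−1, r) + f(j−1, r−1)·exp(η_j)` with analytic gradient and
  Hessian (in C++ via Rcpp), never by subset enumeration; the Breslow
  approximation is available as an option. Output: odds ratios, 95% Wald
  CIs, and an ordinal trend test.

* **Ordered exclusion accounting** (source information → missing
  education → chronology → nonstandard-only histories → unknown
  occupation codes) with a conservation-checked ledger, plus the standard
  battery of sensitivity filters (full employment through the 1–4-year
  window, proxy responses, age > 60, 99th-percentile trimming,
  pre-existing conditions, sex and glioma-grade restriction).

## Worked example

Generate a synthetic study with a true odds ratio of 1.5 in the top
exposure category, then run a small analysis grid:

```r
library(rfjem)
cfg <- synth_config(true_log_or = c(0, 0, 0, log(1.5)))
jm  <- generate_jem(cfg, seed = 1)
jm
#> RF-EMF job-exposure matrix: 936 entries, 468 ISCO88 codes
#>   E fields: 468 codes, 301 exposed (prevalence > 0)
#>   H fields: 468 codes, 301 exposed (prevalence > 0)

syn <- generate_cohort(cfg, jm, seed = 1, n_total = 6000)
run <- run_analysis(syn$participants, syn$jobs, jm,
                    run_config(outcomes = "glioma", fields = "E",
                               methods = c("M1", "M3"), metrics = "cumulative",
                               labels = c("lag1", "lag10")))
res <- run$results
res[res$method == "M1" & res$label == "lag1",
    c("category", "n_cases", "n_controls", "OR", "CI_low", "CI_high", "p_trend")]
#>  category n_cases n_controls    OR CI_low CI_high  p_trend
#>         1     459       1487 0.944  0.771    1.16 1.76e-05
#>         2     265        743 1.089  0.870    1.36 1.76e-05
#>         3     156        445 1.071  0.829    1.38 1.76e-05
#>         4     170        298 1.739  1.338    2.26 1.76e-05
```

Categories 1–4 are the control-percentile bands of cumulative E-field
exposure (lag 1) versus the never-exposed reference; the top-category
estimate 1.74 (95% CI 1.34–2.26) covers the simulated truth of 1.5, and
the trend test picks up the monotone signal. `run$ledger` prints the
exclusion accounting; `run$cutpoints` the percentile cut-points actually
used; `write_run(run, dir)` writes `results.csv`, `cutpoints.csv`,
`exposure_profiles.csv`, `ledger.csv` and `run.log`.

## Layout

| | |
|---|---|
| `R/jem.R` | JEM container, ICNIRP squared ratio, Method-2 threshold |
| `R/cohort.R` | loading, exclusion ledger, reference dates, summaries |
| `R/exposure.R` | yearly series, cumulative/TWA metrics, cohort profiles |
| `R/categorize.R` | control-percentile cut-points and categories |
| `R/clogit.R`, `src/cond_loglik.cpp` | exact conditional logistic regression |
| `R/synthetic.R` | study generator with known truth |
| `R/pipeline.R` | analysis-grid orchestration and sensitivity filters |
| `vignettes/rfjem-methods.Rmd` | model, conventions, design choices |
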