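# vvdyn — transient brain-ventricle-volume dynamics

The volume of the brain's CSF-filled ventricles (VV) is usually treated as a
slow, one-way marker of atrophy. In neuroinflammatory disease it is not:
ventricles expand and contract transiently, on the time scale of weeks, and
those excursions track inflammatory activity. `vvdyn` implements the full
analysis pipeline for studying these dynamics in two settings —

* **Relapsing-remitting MS patients** followed with monthly MRI (13 scans of
  VV plus 8 MRI and 4 clinical covariates): per-subject traces are
  normalised to percent of baseline, compared against the healthy
  scan-rescan band (±6%), classified for *sustained contraction events*,
  and screened for lagged temporal coupling between VV and the other
  parameters.
* **EAE mice** (experimental autoimmune encephalomyelitis) imaged every
  second day: quantification of gadolinium-induced T1 shortening
  (ΔT1 = T1pre − T1post), extraction of per-animal event days, and
  Kaplan-Meier/log-rank comparison of event timing (does ventricle
  expansion precede clinical onset?), plus Spearman correlation of ordinal
  histopathology with imaging.

A synthetic-cohort generator with known ground truth (episode times, lagged
couplings, event days) drives every stage, so the whole pipeline runs,
and is testable, without any external data.

## The statistics at the core

**Event classification.** A subject's trace is
`p_t = 100 (V_t − V_0)/V_0`. An *interval event* is a maximal run of
same-sign consecutive changes of `p` with cumulative magnitude `> θ`
(default θ = 6, the healthy scan-rescan band). A subject is *contracting*
when there are indices `t0 < t1`, `t1 − t0 ≥ 2` intervals, with `p`
non-increasing on `[t0, t1]` and `p(t0) − p(t1) > θ` — a decline sustained
over at least two months with no intervening expansion.

**Cross-correlation screen.** Every series is first-order differenced
(`Δx_t = x_{t+1} − x_t`), stationarity is asserted per series with an
augmented Dickey-Fuller drift regression, and for each subject and each
comparison variable Y the lag-limited CCF is computed as the Pearson
correlation of the aligned overlap `{(Δx_t, Δy_{t+k})}`, `k = −2..+2`
(positive lag: Y follows X). Each coefficient gets the usual two-sided
`t = r√((m−2)/(1−r²))` p-value on `m − 2` df (`m = n − |k|` overlapping
pairs), and Benjamini-Hochberg FDR at 0.05 is applied across the whole
coefficient grid (24 subjects × 12 variables × 5 lags = 1440 coefficients
in the reference design).

**Timing analysis.** Per animal: first day VV exceeds +θ% of baseline, day
of the ΔT1 maximum (earliest on ties), first day the clinical score
reaches 1, day of the weight nadir; events not reached are censored at the
last observation. Event-type timing distributions are compared with the
two-sample log-rank test on Kaplan-Meier estimates.

## Worked example

```r
library(vvdyn)

## a synthetic 24-patient MS cohort with episodic VV dynamics
ms <- generate_ms_cohort(ms_cohort_config(n_patients = 24, seed = 42))

stratify_cohort(ms, threshold = 6)
#> <vv_stratification> 24 subjects at threshold 6%
#>   contracting: 17 (71%), noncontracting: 7; expansion-only: 0
#>   with any above-threshold monthly change: 79%

run_ccf_screen(ms, x_variable = "ventricle_volume")
#> <ccf_screen> ventricle_volume vs 12 variables, lags -2..+2 (24 subjects, FDR pool: all)
#> cross-correlation screen summary
#>   coefficients: 1440 (undefined: 0)
#>   nominal p < alpha: 59; FDR-retained: 0
#>   ADF non-stationary flags: 35; periodicity flags: 52

## EAE timing: ventricle expansion and contrast leakage precede clinical signs
eae <- generate_eae_cohort(eae_cohort_config(n_mice = 12, seed = 42))
eae_timing_analysis(eae)
#> <eae_timing> 12 animals, VV threshold 6%
#>   median days: VV onset 8, dT1 max 8, clinical onset 12, weight nadir 14
#>   log-rank comparisons:
#>     vv_onset vs dt1_max: chisq = 1.76, p = 0.184
#>     vv_onset vs clinical_onset: chisq = 19.9, p = 8.26e-06
#>     ...
#>   histology score vs VV: rho = 0.893 (p = 0.0001); vs dT1: rho = 0.355 (p = 0.2568)
```

Reading the output: 17 of the 24 simulated patients show a sustained
contraction deeper than the 6% healthy band (the generator's episodic
expansion/contraction bumps put most subjects over it); the screen
enumerates the full 1440-coefficient grid and, with no couplings injected,
retains nothing after FDR while 59/1440 ≈ 4% are nominally significant —
the expected false-positive rate. In the EAE arm, VV onset and the ΔT1
peak are statistically indistinguishable (p = 0.18) and both precede
clinical onset by ~4 days (p < 1e-4), with heavier histopathology in
animals with larger ventricles.

The end-to-end entry point `run_full_pipeline()` (also exposed as
`inst/scripts/vvdyn-pipeline.R`) runs simulate → stratify → screen → EAE
timing from one YAML/JSON config and writes every stage output plus a
machine-readable `report.json`.

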