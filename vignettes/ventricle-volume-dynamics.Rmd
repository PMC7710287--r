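---
title: "Models and methods: transient ventricle-volume dynamics"
author: "vvdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: transient ventricle-volume dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vvdyn)
```

This vignette is the package's own account of its models: what each stage
assumes, which tunable parameters matter and why their defaults were
chosen, what the synthetic cohorts do and do not emulate, and the
numerical decisions taken where the design was genuinely open. It states
no empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. Baseline-relative event analysis

All ventricle-volume (VV) analysis happens on the percent-of-baseline
scale, `p_t = 100 (V_t - V_0) / V_0`, where the baseline is always the
first scan; series are never re-baselined. Interval changes are
percentage-point differences of `p`, not month-over-month ratios: the
threshold is a band drawn around the baseline-relative trace, so events
must be measured on the same scale.

**The healthy band.** The one-sided threshold θ defaults to 6%, the
maximum intra-individual scan-rescan fluctuation reported for healthy
adults on monthly schedules. `estimate_normal_variation_threshold()`
replaces the constant with the max-over-subjects of each control's maximum
`|p_t|` when control data are supplied; estimated thresholds are not
rounded. A single constant-VV control produces a zero threshold, which is
flagged as degenerate rather than silently used (every nonzero change
would become an "event").

**Events and contraction status.** An interval event is a maximal run of
same-sign consecutive changes with cumulative magnitude strictly above θ;
a zero-change month terminates a run. A subject is *contracting* when the
trace has a window of at least `min_duration = 2` intervals over which it
is non-increasing and the total drop strictly exceeds θ. "No expansions
in between" is operationalised as non-increasing: a zero month does not
break a contraction, any positive month does. This is the most literal
machine-checkable reading; the alternative (allowing sub-threshold
upticks inside a window) would classify strictly more subjects as
contracting and is not what a band-crossing criterion describes. Windows
may begin at the baseline scan itself — nothing in the definition
privileges later months. Within a maximal non-increasing run the deepest
qualifying window is the whole run, which is what the implementation
scans; the test suite checks equivalence against a brute-force evaluation
of *every* window on every short grid trace.

Subjects with any missing VV value are excluded from stratification with
a warning (a completers-only analysis); they are not imputed, because a
single missing month can hide or fabricate a 2-month window.

## 2. The cross-correlation screen

The screen asks, per subject, whether changes in one series (X, by
default VV) co-occur with or precede/follow changes in each comparison
series Y, within ±2 time steps.

**Differencing.** Every series is first-order differenced before
correlation. This removes linear trends — the dominant nonstationarity in
a 13-month window (slow atrophy, drift in clinical scores) — and is
confirmed per series with an augmented Dickey-Fuller (ADF) drift
regression. ADF failures never abort the screen: stationarity is a
diagnostic here, and failures are counted in the summary so they can be
reported alongside the results.

**ADF details.** The regression is Δy on (1, lagged level, lagged
differences); the statistic is the t-ratio of the lagged level, compared
against the small-sample Dickey-Fuller drift percentiles with bilinear
interpolation in sample size and tail probability. The default lag order
is 0 for differenced lengths up to 14 — a dozen points cannot support
lagged augmentation — with the Schwert rule `trunc(4 (n/100)^(1/4))` for
longer series. The acceptance suite measures the test's size on random
walks (≈5% at n = 100) and its power on white noise (≈1).

**The CCF estimator.** The coefficient at lag k is the Pearson
correlation over the aligned overlap `{(x_t, y_{t+k})}` with
`m = n − |k|` pairs — not the denominator-n stationary-process estimator.
At n = 12 after differencing the stationary estimator's shrinkage toward
zero is material (factor (n−|k|)/n), and the overlap-Pearson form has an
exact finite-sample significance theory and a transparent brute-force
oracle. The denominator-n variant (matching `stats::ccf`) is available
behind `stationary = TRUE` for cross-checking. Sign convention: positive
lag means events in Y follow events in X; the identity
`ccf(X,Y)(k) = ccf(Y,X)(−k)` holds exactly and is tested. A zero-variance
overlap yields an `NA` coefficient that is excluded from the FDR family
and counted, never fabricated.

**Nominal p and the FDR family.** Each coefficient gets the two-sided
`t = r√((m−2)/(1−r²))` p-value on `m − 2` df. Benjamini-Hochberg runs by
default over *all* defined coefficients in the grid (`fdr_pool = "all"`):
BH is defined on a family, and the family here is the full enumerated
grid (e.g. 24 × 12 × 5 = 1440). The two-stage reading — BH applied only
to the nominally significant coefficients — is implemented as
`fdr_pool = "nominal"` so both conventions are reproducible; neither is
claimed to be "the" published computation, and the nominal pool can only
retain more.

**Null calibration, and a caveat about differencing.** The package's null
reference (`generate_null_cohort()`) makes every variable an independent
Gaussian *random walk*, so that the differenced series the CCF actually
consumes are independent white noise. Under that null the nominal p < .05
rate is 5% and the proportion of 24×12×13 cohorts with any FDR-retained
coefficient is ≈α (measured over 500 cohorts in the acceptance suite).
The distinction matters: if instead the observed *levels* are white
noise, differencing manufactures an MA(1) autocorrelation of −0.5 in
every series, Var(r) inflates by roughly 1 + 2(0.5)² = 1.5, and the
nominal rate rises to ≈9% with a many-fold inflation of the family-wise
rate. That variant is kept (`noise = "levels"`) precisely to demonstrate
that differencing data which are already stationary is not innocuous —
a practical caveat for any pipeline that differences unconditionally.

Ordinal variables must not enter the screen; the Pearson machinery
assumes continuous inputs (which is also why disability scales are
carried through the data model but never screened).

## 3. EAE timing

ΔT1 = T1pre − T1post (ms) preserves sign: negative values flag absent net
enhancement and are data, not errors. Event extraction takes the first
day the VV percent trace strictly exceeds +θ, the day of the ΔT1 maximum,
the first day the clinical score reaches 1 (the first nonzero grade), and
the weight-nadir day; argmax/argmin ties resolve to the *earliest* day.
On a 2-3-day observation schedule a tie spans days, and taking the
earliest is conservative for "onset precedes" claims only where it favours
the later-event series equally; the rule is applied uniformly to all four
event types. Unreached events are censored at the last observed day.

Timing distributions of different event types within the same animals are
compared with the two-sample log-rank test, as the study design this
package follows did. This treats paired times as independent samples — a
fidelity choice, preserved deliberately; the paired Wilcoxon signed-rank
alternative is computed alongside when `paired_alternative = TRUE` but is
off by default. Similarly, one-way ANOVA across longitudinal time points
ignores within-animal correlation; `one_way_anova()` reproduces the
stated test and deliberately does not substitute a mixed model.

Exact rank tests: the signed-rank p is the exact sign-permutation
probability for up to 25 nonzero pairs, computed by convolution on the
tied-rank statistic so it remains exact under ties; Mann-Whitney is exact
(via the null U distribution) for tie-free groups of up to 10; Spearman's
p enumerates all n! permutations for n ≤ 8 (tie-aware). Beyond those
sizes the standard normal/t approximations with tie corrections apply.
The thresholds are where enumeration stops being cheap, not statistical
judgments.

## 4. What the generators emulate — and what they do not

The generators define the study conditions under which every property in
the test suite is evaluated.

**Healthy controls** (`generate_healthy_cohort`): `V_t = B (1 + ε_t)`,
`ε_0 = 0`, `ε_t ~ N(0, σ)` independent; default σ = 1.5% — a realistic
scan-rescan coefficient of variation for ventricular segmentation, and
comfortably inside the 6% band (3σ = 4.5%). Default 6 subjects, 7 monthly
scans, baselines uniform on 25-42 mL, matching the shape of a small
serial-MRI control study.

**MS patients** (`generate_ms_cohort`): VV is
`B (1 + drift·t + Σ bumps + ε_t)` with a slow default drift of 0.05%/month,
fractional noise σ = 1%, and, with probability 0.7 per patient, one
piecewise-linear episode (rise 1-3 months, fall 1-3 months, amplitude
8-25% of baseline). Piecewise-linear is the simplest shape matching a
rise-peak-return excursion; smooth shapes would change nothing tested.
Covariates are `location + scale·(coupled signal + AR(1) noise)` with AR
coefficient 0.3 (clinical scores show serial dependence); lesion counts
are Poisson with a log-link to their coupled driver and lesion volume is
count × lognormal per-lesion sizes, so counts stay nonnegative integers.
Ground-truth couplings (`coupling_spec`) inject
`coefficient × standardised driver(t − lag)` into a target, which is what
the recovery tests invert. Episode amplitudes are ranges chosen for
testability — the literature gives no quantitative distribution for
inter-individual episode amplitude, only that some patients are volatile.

**EAE mice** (`generate_eae_cohort`): clinical onset ~ N(11, 1.5) days
(truncated positive), VV rising from `onset − lead` (lead 3-5 d) to a
peak of 40-80% above baseline just after onset and resolving by ~11 days
later; ΔT1 a Gaussian pulse (SD 2.5 d, peak 300-700 ms) centred ~2 days
before onset; score 0 before onset rising to 3 and remitting; weight
proportional to score. These reproduce the relapsing SJL kinetics that
motivate the timing analysis: expansion and peak enhancement precede
clinical signs by several days. Ground-truth event days are computed
analytically from the noise-free trajectories on the observation
schedule — not by running the extractor — so exact recovery is a real
check, not a tautology.

**Seeding.** One integer seed expands into per-subject substreams
(`seed + 104729·i mod 2³¹−1`), so enlarging a cohort never perturbs
existing subjects, and identical configs give byte-identical serialized
tables (asserted in the tests).

**Not emulated:** scanner/segmentation systematics (drift, field-strength
effects, re-positioning bias), informative missingness (masking is
uniform), treatment effects, within-cohort correlation between patients,
and any image-level process — volumes, ΔT1 means and histology grades
enter as numbers. Passing tests therefore demonstrate the *statistical
machinery* is correct and calibrated under the stated models, not that
real MRI data meet those models.

## 5. Numerical choices and degenerate inputs

* Thresholds are strict inequalities throughout (`> θ`, score `≥ 1`),
  matching "beyond the threshold" phrasing.
* `max_contraction` is 0 (not `NA`) when no qualifying window exists; the
  per-subject lollipop depth uses the deepest non-increasing run of any
  length, so noncontracting subjects still plot.
* Undefined CCF records (constant overlap) are excluded from the BH
  family; q-values of excluded records are `NA` and never significant.
* The ADF p-value is clamped to the tabulated range [0.01, 0.99].
* CSVs are written with 17 significant digits so cohort round trips are
  bit-exact; the run report isolates its timestamp in a single field so
  reports are otherwise byte-identical under a fixed seed.
* Problem sizes in the heavy property checks — 500 null cohorts, 200
  coupling-recovery and 200 EAE-detection replicates, 500-replicate ADF
  calibration, 1000-subject healthy band — were chosen to put Monte-Carlo
  standard errors well inside the asserted margins while keeping the full
  suite around five minutes on one CPU.

## 6. Known limitations

The 6% band is a population-level constant; per-subject thresholds would
need repeated healthy scans per individual. The t-based CCF p-values
assume the differenced series are serially uncorrelated — the ACF check
flags violations but the screen does not model them. The log-rank
comparison of paired event types inherits the original design's
independence approximation. And the contraction classifier is sensitive
to single-month data errors by construction (a spurious positive month
breaks a window), which is the flip side of its strict "no expansions in
between" definition.
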