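# Synthetic cohorts with the statistical structure the downstream analyses
# assume: healthy scan-rescan fluctuation, episodic MS ventricle dynamics with
# optional lagged couplings between variables, and EAE trajectories whose
# ventricle/contrast events precede clinical onset. Every generator records
# its ground truth (event times, couplings) so recovery is testable.

# sample() that never auto-expands a scalar into 1:x
draw_one <- function(v) v[sample.int(length(v), 1L)]

# Deterministic per-subject substream: adding subjects to a cohort never
# perturbs the series of existing ones.
substream_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) + 104729 * as.double(index)
  as.integer(s %% 2147483647)
}

#' Specify a ground-truth lagged coupling between two generated variables
#'
#' A positive lag means the target's events follow the driver's by `lag` time
#' steps; the coefficient is a standardized coupling strength in [-1, 1].
#'
#' @param driver_variable,target_variable Variable names (must differ).
#' @param lag Integer time-step offset; `|lag| <= max_lag`.
#' @param coefficient Standardized strength in `[-1, 1]`.
#' @param max_lag Largest admissible `|lag|`.
#' @return A list of class `coupling_spec`.
#' @export
coupling_spec <- function(driver_variable, target_variable, lag, coefficient,
                          max_lag = 5L) {
  if (identical(driver_variable, target_variable)) {
    stop("coupling driver and target must differ")
  }
  lag <- as.integer(lag)
  if (abs(lag) > max_lag) stop("coupling |lag| exceeds max_lag = ", max_lag)
  if (abs(coefficient) > 1) stop("coupling coefficient must lie in [-1, 1]")
  structure(list(driver_variable = driver_variable,
                 target_variable = target_variable,
                 lag = lag, coefficient = coefficient),
            class = "coupling_spec")
}

#' Configuration for the synthetic relapsing-remitting MS cohort
#'
#' Defaults mirror the monthly-MRI study design the package analyses: 13
#' monthly scans of ventricle volume (mm^3) plus 8 MRI and 4 clinical
#' covariates per patient. Ventricle series combine a slow atrophy drift,
#' episodic expansion/contraction bumps (piecewise-linear rise and fall) and
#' fractional Gaussian noise; covariates carry AR(1) noise and any configured
#' lagged couplings to a driver series.
#'
#' @param n_patients Number of patients.
#' @param n_timepoints Number of monthly scans (>= 5).
#' @param baseline_vv_range Uniform range for baseline ventricle volume, mm^3.
#' @param atrophy_drift Fractional VV change per month (positive = slow
#'   enlargement).
#' @param episode_params List: `prob` (per-subject episode probability),
#'   `amp_range` (bump amplitude as fraction of baseline), `rise`, `fall`
#'   (integer ranges of rise/fall durations in months).
#' @param noise_sd Fractional Gaussian noise SD on VV.
#' @param couplings List of [coupling_spec()] objects.
#' @param covariate_baselines Named list of `c(location, scale)` per covariate.
#' @param ar_coefficient AR(1) coefficient of covariate noise, in (-1, 1).
#' @param covariate_noise_sd SD of the AR(1) covariate noise relative to a
#'   unit-variance coupled signal (1 = noise and signal on the same scale).
#' @param mask_rate Fraction of non-baseline cells masked to `NA`.
#' @param seed Integer seed.
#' @return A validated list of class `ms_cohort_config`.
#' @export
ms_cohort_config <- function(n_patients = 24L,
                             n_timepoints = 13L,
                             baseline_vv_range = c(25000, 42000),
                             atrophy_drift = 0.0005,
                             episode_params = list(prob = 0.7,
                                                   amp_range = c(0.08, 0.25),
                                                   rise = c(1L, 3L),
                                                   fall = c(1L, 3L),
                                                   onset = NULL),
                             noise_sd = 0.01,
                             couplings = list(),
                             covariate_baselines = default_ms_covariates(),
                             ar_coefficient = 0.3,
                             covariate_noise_sd = 1,
                             mask_rate = 0,
                             seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_timepoints = as.integer(n_timepoints),
              baseline_vv_range = baseline_vv_range,
              atrophy_drift = atrophy_drift,
              episode_params = episode_params,
              noise_sd = noise_sd,
              couplings = couplings,
              covariate_baselines = covariate_baselines,
              ar_coefficient = ar_coefficient,
              covariate_noise_sd = covariate_noise_sd,
              mask_rate = mask_rate,
              seed = as.integer(seed))
  if (cfg$n_timepoints < 5L) stop("n_timepoints must be >= 5")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(cfg$baseline_vv_range <= 0)) stop("baseline VV range must be positive")
  if (any(episode_params$amp_range <= 0)) stop("episode amplitudes must be > 0")
  if (abs(ar_coefficient) >= 1) stop("ar_coefficient must lie in (-1, 1)")
  for (cp in couplings) {
    if (!inherits(cp, "coupling_spec")) stop("couplings must be coupling_spec objects")
    if (abs(cp$lag) > cfg$n_timepoints - 3L) {
      stop("coupling lag ", cp$lag, " leaves no estimable overlap for ",
           cfg$n_timepoints, " time points")
    }
  }
  structure(cfg, class = "ms_cohort_config")
}

# Location/scale of the 12 non-VV covariates: counts and volumes in the units
# radiologists report (mm^3), ADC in 10^-3 mm^2/s, test scores in their
# native units.
default_ms_covariates <- function() {
  list(
    cel_count  = c(1.5, 0.4),     # Poisson base rate; scale modulates log-rate
    cel_volume = c(120, 0.5),     # mean per-lesion volume mm^3; lognormal sdlog
    t2_volume  = c(12000, 900),
    bh_volume  = c(2500, 220),
    adc_cc     = c(0.80, 0.03),
    adc_bg     = c(0.76, 0.025),
    adc_bs     = c(0.78, 0.025),
    adc_wm     = c(0.82, 0.03),
    pasat      = c(48, 3),
    hpt_dom    = c(20, 1.5),
    hpt_ndom   = c(22, 1.8),
    twt        = c(6, 0.5)
  )
}

#' Generate a healthy scan-rescan cohort
#'
#' Each subject's ventricle-volume series is `baseline * (1 + eps_t)` with
#' `eps_0 = 0` and independent Gaussian fluctuations of the stated fractional
#' SD thereafter, emulating repeated imaging of stable healthy anatomy.
#'
#' @param n_subjects Number of subjects.
#' @param n_timepoints Number of scans (>= 2).
#' @param baseline_range Uniform range for baseline VV, mm^3.
#' @param fluctuation_sd Fractional SD of the scan-rescan fluctuation (>= 0).
#' @param seed Integer seed.
#' @return A [vv_cohort()] of healthy subjects with a `ventricle_volume`
#'   series each.
#' @export
generate_healthy_cohort <- function(n_subjects = 6L, n_timepoints = 7L,
                                    baseline_range = c(25000, 42000),
                                    fluctuation_sd = 0.015, seed = 1L) {
  if (fluctuation_sd < 0) stop("fluctuation_sd must be >= 0")
  if (n_timepoints < 2L) stop("n_timepoints must be >= 2")
  if (any(baseline_range <= 0)) stop("baseline range must be positive")
  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    set.seed(substream_seed(seed, i))
    baseline <- stats::runif(1, baseline_range[1], baseline_range[2])
    eps <- c(0, stats::rnorm(n_timepoints - 1L, 0, fluctuation_sd))
    vv <- baseline * (1 + eps)
    if (any(vv <= 0)) stop("fluctuation produced nonpositive volume; lower fluctuation_sd")
    subjects[[i]] <- subject_series(
      sprintf("HC%02d", i), "healthy", seq_len(n_timepoints) - 1L,
      list(ventricle_volume = vv), time_unit = "months")
  }
  vv_cohort(subjects)
}

# Piecewise-linear episode bump: 0 before onset, linear rise to `amp` over
# `rise` steps, linear fall back to 0 over `fall` steps.
episode_bump <- function(t, onset, amp, rise, fall) {
  peak <- onset + rise
  end <- peak + fall
  up <- t > onset & t <= peak
  down <- t > peak & t < end
  b <- numeric(length(t))
  b[up] <- amp * (t[up] - onset) / rise
  b[down] <- amp * (end - t[down]) / fall
  b[t == peak] <- amp
  b
}

#' Generate a synthetic MS patient cohort
#'
#' Ventricle volume is `baseline * (1 + drift*t + sum(episode bumps) + eps_t)`.
#' Continuous covariates are `location + scale * (coupled signal + AR(1)
#' noise)`; contrast-enhancing-lesion (CEL) counts are Poisson with a log-link
#' to their coupled driver (or to AR(1) noise when uncoupled) and CEL volume
#' is the count times lognormal per-lesion sizes. Ground truth (episodes,
#' couplings) is attached to the returned cohort.
#'
#' @param config An [ms_cohort_config()].
#' @return A [vv_cohort()] with ground truth in `attr(, "ground_truth")`.
#' @export
generate_ms_cohort <- function(config = ms_cohort_config()) {
  stopifnot(inherits(config, "ms_cohort_config"))
  nt <- config$n_timepoints
  tgrid <- seq_len(nt) - 1L
  cov_names <- names(config$covariate_baselines)
  subjects <- vector("list", config$n_patients)
  gt_episodes <- list()
  for (i in seq_len(config$n_patients)) {
    set.seed(substream_seed(config$seed, i))
    id <- sprintf("MS%02d", i)
    baseline <- stats::runif(1, config$baseline_vv_range[1],
                             config$baseline_vv_range[2])
    ep <- config$episode_params
    bump <- numeric(nt)
    episodes <- NULL
    if (stats::runif(1) < ep$prob) {
      rise <- draw_one(seq(ep$rise[1], ep$rise[2]))
      fall <- draw_one(seq(ep$fall[1], ep$fall[2]))
      onset <- if (is.null(ep$onset)) {
        draw_one(seq(1L, max(1L, nt - rise - fall - 1L)))
      } else as.integer(ep$onset)
      amp <- stats::runif(1, ep$amp_range[1], ep$amp_range[2])
      bump <- episode_bump(tgrid, onset, amp, rise, fall)
      episodes <- data.frame(subject_id = id, onset = onset,
                             peak = onset + rise, end = onset + rise + fall,
                             amplitude = amp)
    }
    eps <- c(0, stats::rnorm(nt - 1L, 0, config$noise_sd))
    vv <- baseline * (1 + config$atrophy_drift * tgrid + bump + eps)
    if (any(vv <= 0)) stop("MS generator produced nonpositive VV; check config")
    vars <- list(ventricle_volume = vv)

    # coupled signal per target: sum of coef * standardized driver(t - lag)
    signal_for <- function(target) {
      sig <- numeric(nt)
      for (cp in config$couplings) {
        if (cp$target_variable != target) next
        drv <- vars[[cp$driver_variable]]
        if (is.null(drv)) {
          stop("coupling driver '", cp$driver_variable,
               "' must be generated before target '", target, "'")
        }
        z <- as.numeric(scale(drv))
        pos <- tgrid - cp$lag + 1L      # 1-based position of driver(t - lag)
        valid <- pos >= 1L & pos <= nt
        shifted <- numeric(nt)
        shifted[valid] <- z[pos[valid]]
        sig <- sig + cp$coefficient * shifted
      }
      sig
    }
    ar1 <- function() {
      phi <- config$ar_coefficient
      z <- stats::rnorm(nt)
      e <- numeric(nt)
      e[1] <- z[1]
      for (t in seq(2, nt)) e[t] <- phi * e[t - 1L] + sqrt(1 - phi^2) * z[t]
      e
    }

    cel_par <- config$covariate_baselines$cel_count
    cel_sig <- signal_for("cel_count") + signal_for("cel_volume")
    cel_noise_sd <- if (all(cel_sig == 0)) cel_par[2] else
      0.1 * config$covariate_noise_sd
    rate <- exp(log(cel_par[1]) + cel_sig + cel_noise_sd * ar1())
    count <- stats::rpois(nt, rate)
    vars$cel_count <- count

    size_par <- config$covariate_baselines$cel_volume
    sizes <- stats::rlnorm(nt, meanlog = log(size_par[1]), sdlog = size_par[2])
    vars$cel_volume <- count * sizes

    for (nm in setdiff(cov_names, c("cel_count", "cel_volume"))) {
      par <- config$covariate_baselines[[nm]]
      vars[[nm]] <- par[1] +
        par[2] * (signal_for(nm) + config$covariate_noise_sd * ar1())
    }

    if (config$mask_rate > 0) {
      for (nm in names(vars)) {
        mask <- stats::runif(nt) < config$mask_rate
        mask[1] <- FALSE  # keep the baseline scan observed
        vars[[nm]][mask] <- NA_real_
      }
    }
    subjects[[i]] <- subject_series(id, "ms", tgrid, vars, time_unit = "months")
    if (!is.null(episodes)) gt_episodes[[length(gt_episodes) + 1L]] <- episodes
  }
  truth <- list(
    episodes = if (length(gt_episodes)) do.call(rbind, gt_episodes) else NULL,
    couplings = lapply(config$couplings, unclass),
    atrophy_drift = config$atrophy_drift
  )
  vv_cohort(subjects, ground_truth = truth)
}

#' Generate a global-null cohort with no cross-variable structure
#'
#' The no-temporal-relationship reference condition for calibrating the
#' cross-correlation screen's false-discovery control. The screen operates
#' on first-differenced series, so the null that matches its sampling theory
#' is `noise = "innovations"` (default): every variable is an independent
#' Gaussian random walk, making the differenced series the screen analyses
#' independent white noise. `noise = "levels"` instead makes the observed
#' levels themselves white noise; differencing then induces an MA(1)
#' autocorrelation of -0.5 in every series, which visibly inflates the
#' nominal significance rate of the CCF — useful for demonstrating why
#' differencing already-stationary data is not innocuous, but not a
#' calibrated null for the screen.
#'
#' @param n_subjects,n_variables,n_timepoints Cohort dimensions; the first
#'   variable is named `ventricle_volume` so the cohort drops straight into
#'   [run_ccf_screen()].
#' @param noise `"innovations"` (independent increments; differenced series
#'   are white) or `"levels"` (independent observations).
#' @param seed Integer seed.
#' @return A [vv_cohort()].
#' @export
generate_null_cohort <- function(n_subjects = 24L, n_variables = 13L,
                                 n_timepoints = 13L,
                                 noise = c("innovations", "levels"),
                                 seed = 1L) {
  noise <- match.arg(noise)
  vnames <- c("ventricle_volume",
              sprintf("var%02d", seq_len(n_variables - 1L)))
  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    set.seed(substream_seed(seed, i))
    vars <- lapply(vnames, function(v) {
      z <- stats::rnorm(n_timepoints)
      100 + if (noise == "innovations") cumsum(z) else z
    })
    names(vars) <- vnames
    subjects[[i]] <- subject_series(sprintf("N%02d", i), "ms",
                                    seq_len(n_timepoints) - 1L, vars,
                                    time_unit = "months")
  }
  vv_cohort(subjects)
}

#' Configuration for the synthetic EAE mouse cohort
#'
#' Defaults emulate relapsing EAE in SJL mice imaged every second day from a
#' pre-immunization baseline: clinical signs emerge around day 10-12 post
#' immunization, ventricle volume expands dramatically (tens of percent)
#' several days before onset and remits by about day 22, contrast-induced T1
#' shortening (delta-T1, ms) peaks shortly before onset, and body weight dips
#' with the clinical peak.
#'
#' @param n_mice Number of animals.
#' @param schedule_days Strictly increasing observation days; the first
#'   (baseline) day must precede immunization day 0.
#' @param vv_peak List: `lead_range` (days VV starts rising before clinical
#'   onset), `amp_range` (peak expansion as a fraction of baseline),
#'   `resolve_days` (days from onset until VV returns to baseline).
#' @param dt1_peak List: `lead_mean`, `lead_sd` (days the delta-T1 peak
#'   precedes onset), `width` (Gaussian pulse SD, days), `range_ms` (peak
#'   amplitude, ms).
#' @param clinical_onset List: `mean`, `sd`, `min_day` (> 0) of the onset-day
#'   distribution; `peak_score`, `peak_offset` (days onset to peak),
#'   `remit_days`.
#' @param weight_loss List: `baseline_range` (g), `coef` (fractional loss per
#'   score unit at peak score).
#' @param noise List of `vv` (fractional), `dt1` (ms), `weight` (g) SDs.
#' @param histo_breaks Day cut points mapping sacrifice day to the ordinal
#'   inflammation score 0-3.
#' @param seed Integer seed.
#' @return A validated list of class `eae_cohort_config`.
#' @export
eae_cohort_config <- function(n_mice = 10L,
                              schedule_days = c(-2, seq(0, 40, by = 2)),
                              vv_peak = list(lead_range = c(3, 5),
                                             amp_range = c(0.4, 0.8),
                                             resolve_days = 11),
                              dt1_peak = list(lead_mean = 2, lead_sd = 0.8,
                                              width = 2.5,
                                              range_ms = c(300, 700)),
                              clinical_onset = list(mean = 11, sd = 1.5,
                                                    min_day = 3,
                                                    peak_score = 3,
                                                    peak_offset = 3,
                                                    remit_days = 10),
                              weight_loss = list(baseline_range = c(18, 22),
                                                 coef = 0.05),
                              noise = list(vv = 0.02, dt1 = 20, weight = 0.15),
                              histo_breaks = c(3, 8, 11),
                              seed = 1L) {
  if (any(diff(schedule_days) <= 0)) stop("schedule_days must be strictly increasing")
  if (schedule_days[1] >= 0) stop("baseline day must precede immunization day 0")
  if (clinical_onset$min_day <= 0) {
    stop("clinical onset distribution must not allow onset on or before day 0")
  }
  if (any(unlist(noise) < 0)) stop("noise SDs must be >= 0")
  structure(list(n_mice = as.integer(n_mice), schedule_days = schedule_days,
                 vv_peak = vv_peak, dt1_peak = dt1_peak,
                 clinical_onset = clinical_onset, weight_loss = weight_loss,
                 noise = noise, histo_breaks = histo_breaks,
                 seed = as.integer(seed)),
            class = "eae_cohort_config")
}

# Noise-free EAE trajectories for one animal, on the observation schedule.
eae_trajectories <- function(days, onset, lead, amp, resolve, dt1_center,
                             dt1_amp, dt1_width, peak_score, peak_offset,
                             remit_days, wt_base, wt_coef) {
  rise_start <- onset - lead
  peak_day <- onset + 1
  bump <- numeric(length(days))
  up <- days > rise_start & days <= peak_day
  down <- days > peak_day & days < onset + resolve
  bump[up] <- amp * (days[up] - rise_start) / (peak_day - rise_start)
  bump[down] <- amp * (onset + resolve - days[down]) / (onset + resolve - peak_day)

  dt1 <- dt1_amp * exp(-0.5 * ((days - dt1_center) / dt1_width)^2)
  dt1[days < 0] <- 0  # no contrast leakage before immunization

  score <- numeric(length(days))
  post <- days >= onset
  up_sc <- post & days <= onset + peak_offset
  score[up_sc] <- 1 + (peak_score - 1) * (days[up_sc] - onset) / peak_offset
  down_sc <- post & days > onset + peak_offset
  score[down_sc] <- pmax(0, peak_score * (1 - (days[down_sc] - onset - peak_offset) /
                                            remit_days))
  score <- round(score * 2) / 2  # scored on a half-point scale

  weight <- wt_base * (1 - wt_coef * score / peak_score)
  list(bump = bump, dt1 = dt1, score = score, weight = weight)
}

#' Generate a synthetic EAE cohort with known event days
#'
#' Per animal, the ventricle-volume percent trace rises above baseline before
#' the clinical-onset day, delta-T1 peaks at its configured day, the clinical
#' score is 0 before onset and rises to a peak before remitting, and weight
#' dips with the clinical peak. Ground-truth event days (computed analytically
#' from the noise-free trajectories, censored at the last observation day when
#' not reached) and a histology table are attached to the cohort.
#'
#' @param config An [eae_cohort_config()].
#' @param vv_threshold Percent-of-baseline threshold defining the ground-truth
#'   VV-onset day (default 6).
#' @return A [vv_cohort()] of EAE animals with variables
#'   `ventricle_volume, dt1_whole_brain, dt1_cerebellum, score, weight`;
#'   ground truth in `attr(, "ground_truth")`.
#' @export
generate_eae_cohort <- function(config = eae_cohort_config(), vv_threshold = 6) {
  stopifnot(inherits(config, "eae_cohort_config"))
  days <- config$schedule_days
  last_day <- days[length(days)]
  subjects <- vector("list", config$n_mice)
  gt <- vector("list", config$n_mice)
  histo <- vector("list", config$n_mice)
  for (i in seq_len(config$n_mice)) {
    set.seed(substream_seed(config$seed, i))
    co <- config$clinical_onset
    onset <- max(co$min_day, stats::rnorm(1, co$mean, co$sd))
    vp <- config$vv_peak
    lead <- stats::runif(1, vp$lead_range[1], vp$lead_range[2])
    amp <- stats::runif(1, vp$amp_range[1], vp$amp_range[2])
    dp <- config$dt1_peak
    dt1_center <- onset - max(0.5, stats::rnorm(1, dp$lead_mean, dp$lead_sd))
    dt1_amp <- stats::runif(1, dp$range_ms[1], dp$range_ms[2])
    wl <- config$weight_loss
    wt_base <- stats::runif(1, wl$baseline_range[1], wl$baseline_range[2])

    tr <- eae_trajectories(days, onset, lead, amp, vp$resolve_days,
                           dt1_center, dt1_amp, dp$width,
                           co$peak_score, co$peak_offset, co$remit_days,
                           wt_base, wl$coef)
    baseline_vv <- stats::runif(1, 8, 12)  # mouse ventricular system, mm^3
    nz <- config$noise
    vv <- baseline_vv * (1 + tr$bump) *
      (1 + c(0, stats::rnorm(length(days) - 1L, 0, nz$vv)))
    dt1_wb <- tr$dt1 + stats::rnorm(length(days), 0, nz$dt1)
    dt1_cb <- 1.3 * tr$dt1 + stats::rnorm(length(days), 0, nz$dt1)
    weight <- tr$weight + stats::rnorm(length(days), 0, nz$weight)

    id <- sprintf("EAE%02d", i)
    subjects[[i]] <- subject_series(
      id, "eae", days,
      list(ventricle_volume = vv, dt1_whole_brain = dt1_wb,
           dt1_cerebellum = dt1_cb, score = tr$score, weight = weight),
      time_unit = "days")

    # analytic ground truth on the observation schedule, earliest-day ties
    cross <- days[100 * tr$bump > vv_threshold]
    t_vv <- if (length(cross)) cross[1] else last_day
    t_dt1 <- days[which.max(tr$dt1)]
    onset_days <- days[tr$score >= 1]
    t_clin <- if (length(onset_days)) onset_days[1] else last_day
    t_wt <- days[which.min(tr$weight)]
    gt[[i]] <- data.frame(
      animal_id = id,
      t_vv_onset = t_vv, vv_censored = !length(cross),
      t_dt1_max = t_dt1, dt1_censored = FALSE,
      t_clinical_onset = t_clin, clinical_censored = !length(onset_days),
      t_weight_nadir = t_wt, weight_censored = FALSE,
      stringsAsFactors = FALSE
    )
    # sacrifice during the pre-onset / peak phase, where histopathology is
    # graded; inflammation score is a monotone step function of day
    early <- days[days >= days[1] & days <= 14]
    sac <- draw_one(early)
    histo[[i]] <- data.frame(
      animal_id = id, sacrifice_day = sac,
      score = findInterval(sac, config$histo_breaks),
      vv_at_sacrifice = 100 * (1 + tr$bump[match(sac, days)]),
      dt1_at_sacrifice = tr$dt1[match(sac, days)],
      stringsAsFactors = FALSE
    )
  }
  truth <- list(event_days = do.call(rbind, gt),
                histology = do.call(rbind, histo),
                vv_threshold = vv_threshold)
  vv_cohort(subjects, ground_truth = truth)
}
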