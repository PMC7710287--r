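test_that("healthy generator honours the zero-noise and determinism contracts", {
  h0 <- generate_healthy_cohort(4, 6, fluctuation_sd = 0, seed = 2)
  for (s in h0) {
    expect_equal(diff(range(s$variables$ventricle_volume)), 0)
  }
  a <- generate_healthy_cohort(6, 7, seed = 1)
  b <- generate_healthy_cohort(6, 7, seed = 1)
  expect_identical(cohort_to_table(a), cohort_to_table(b))
  # byte-wise on the serialized table
  fa <- withr::local_tempfile(fileext = ".csv")
  fb <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(a, fa); write_cohort_csv(b, fb)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fb, "raw", file.size(fb)))
  expect_error(generate_healthy_cohort(2, 5, baseline_range = c(-1, 5)),
               "positive")
})

test_that("per-subject substreams leave existing subjects untouched", {
  small <- generate_healthy_cohort(3, 7, seed = 9)
  big <- generate_healthy_cohort(6, 7, seed = 9)
  for (id in names(small)) {
    expect_identical(small[[id]], big[[id]])
  }
})

test_that("healthy exceedance fraction matches the Gaussian closed form", {
  sd <- 0.02; nt <- 7L
  h <- generate_healthy_cohort(4000, nt, fluctuation_sd = sd, seed = 5)
  frac <- mean(vapply(h, function(s) {
    max(abs(percent_change_from_baseline(s$variables$ventricle_volume))) > 6
  }, TRUE))
  # P(max |eps_t| > 0.06) over nt-1 iid N(0, sd) fluctuations
  expected <- 1 - (2 * pnorm(0.06 / sd) - 1)^(nt - 1L)
  mc_se <- sqrt(expected * (1 - expected) / 4000)
  expect_lt(abs(frac - expected), 4 * mc_se)
})

test_that("MS generator: flat limit, episode construction, validation", {
  flat <- generate_ms_cohort(ms_cohort_config(
    n_patients = 3, atrophy_drift = 0, noise_sd = 0,
    episode_params = list(prob = 0, amp_range = c(0.1, 0.2),
                          rise = c(1, 2), fall = c(1, 2)), seed = 4))
  for (s in flat) {
    expect_equal(diff(range(s$variables$ventricle_volume)), 0)
  }
  one <- generate_ms_cohort(ms_cohort_config(
    n_patients = 1, atrophy_drift = 0, noise_sd = 0,
    episode_params = list(prob = 1, amp_range = c(0.2, 0.2),
                          rise = c(2, 2), fall = c(3, 3), onset = 3),
    seed = 4))
  pct <- percent_change_from_baseline(one[[1]]$variables$ventricle_volume)
  expect_equal(which.max(pct) - 1L, 5L)   # peaks at step onset + rise = 5
  expect_equal(max(pct), 20)
  expect_error(ms_cohort_config(n_timepoints = 4), ">= 5")
  expect_error(ms_cohort_config(
    couplings = list(coupling_spec("a", "b", 11, 0.5, max_lag = 20))),
    "overlap")
  expect_error(coupling_spec("a", "a", 1, 0.5), "must differ")
})

test_that("MS ground truth marks injected episodes and couplings", {
  cfg <- ms_cohort_config(n_patients = 10, seed = 6,
                          couplings = list(coupling_spec(
                            "ventricle_volume", "t2_volume", 1, 0.8)))
  ms <- generate_ms_cohort(cfg)
  gt <- attr(ms, "ground_truth")
  expect_true(all(gt$episodes$subject_id %in% names(ms)))
  expect_equal(gt$couplings[[1]]$lag, 1L)
  # an episode's peak is visible in the subject's percent trace
  ep <- gt$episodes[1L, ]
  pct <- percent_change_from_baseline(
    ms[[ep$subject_id]]$variables$ventricle_volume)
  expect_gt(pct[ep$peak + 1L], 100 * ep$amplitude / 2)
})

test_that("EAE generator: flat limit, event ordering, validation", {
  quiet <- eae_cohort_config(
    n_mice = 4, vv_peak = list(lead_range = c(3, 5), amp_range = c(1e-9, 2e-9),
                               resolve_days = 11),
    noise = list(vv = 0, dt1 = 0, weight = 0), seed = 3)
  co <- generate_eae_cohort(quiet)
  for (s in co) {
    expect_equal(diff(range(s$variables$ventricle_volume)) /
                   s$variables$ventricle_volume[1], 0, tolerance = 1e-6)
  }
  expect_error(eae_cohort_config(schedule_days = c(0, 2, 4)), "baseline")
  expect_error(eae_cohort_config(clinical_onset = list(
    mean = 11, sd = 1.5, min_day = 0, peak_score = 3, peak_offset = 3,
    remit_days = 10)), "onset")

  co2 <- generate_eae_cohort(eae_cohort_config(
    n_mice = 30, noise = list(vv = 0, dt1 = 0, weight = 0), seed = 8))
  gt <- attr(co2, "ground_truth")$event_days
  expect_true(all(gt$t_vv_onset <= gt$t_clinical_onset))
  sched <- co2[[1]]$time
  expect_true(all(unlist(gt[, c("t_vv_onset", "t_dt1_max",
                                "t_clinical_onset", "t_weight_nadir")]) %in%
                    sched))
  # histology score nondecreasing in sacrifice day
  h <- attr(co2, "ground_truth")$histology
  h <- h[order(h$sacrifice_day), ]
  expect_true(all(diff(h$score) >= 0))
})

test_that("healthy cohorts stay inside the 6% band almost surely", {
  # 3 * fluctuation_sd (4.5%) < 6%: nearly all subjects show no
  # above-threshold event and none classify as contracting
  h <- generate_healthy_cohort(1500, 7, fluctuation_sd = 0.015, seed = 88)
  pcts <- lapply(h, function(s)
    percent_change_from_baseline(s$variables$ventricle_volume))
  no_event <- vapply(pcts, function(p)
    nrow(detect_interval_changes(p, 6)) == 0L, TRUE)
  noncontracting <- vapply(pcts, function(p)
    classify_contraction_status(p, 6)$status == "noncontracting", TRUE)
  expect_gte(mean(no_event), 0.95)
  expect_gte(mean(noncontracting), 0.95)
})

test_that("null cohort is reproducible and structure-free in expectation", {
  a <- generate_null_cohort(seed = 2)
  b <- generate_null_cohort(seed = 2)
  expect_identical(cohort_to_table(a), cohort_to_table(b))
  expect_equal(length(a), 24L)
  expect_equal(length(a[[1]]$variables), 13L)
})
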