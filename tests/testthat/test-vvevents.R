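test_that("percent change from baseline follows the definition", {
  expect_equal(percent_change_from_baseline(c(100, 130)), c(0, 30))
  expect_equal(percent_change_from_baseline(rep(42, 5)), rep(0, 5))
  expect_equal(percent_change_from_baseline(c(33500, 33784)),
               c(0, 0.8478), tolerance = 1e-4)
  expect_error(percent_change_from_baseline(c(0, 10)), "baseline")
  expect_error(percent_change_from_baseline(c(NA, 10)), "baseline")
  expect_error(percent_change_from_baseline(100), "2 time points")
})

test_that("healthy-variation threshold is the max of per-subject maxima", {
  mk <- function(id, pcts) subject_series(
    id, "healthy", seq_along(pcts) - 1L,
    list(ventricle_volume = 1000 * (1 + pcts / 100)))
  co <- vv_cohort(list(mk("a", c(0, 3.1, -2)), mk("b", c(0, -5.8, 1)),
                       mk("c", c(0, 4.2, 4.0))))
  est <- estimate_normal_variation_threshold(co)
  expect_equal(est$value, 5.8)
  expect_equal(sort(est$per_subject_maxima), c(3.1, 4.2, 5.8))
  expect_equal(est$source, "estimated")

  expect_warning(
    z <- estimate_normal_variation_threshold(
      vv_cohort(list(mk("flat", c(0, 0, 0))))),
    "degenerate")
  expect_equal(z$value, 0)

  fixed <- estimate_normal_variation_threshold(NULL)
  expect_equal(fixed$value, 6)
  expect_equal(fixed$source, "fixed")
})

test_that("interval events are maximal same-sign runs above threshold", {
  ev <- detect_interval_changes(c(0, 8, 8), 6)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$direction, "expansion")
  expect_equal(ev$magnitude, 8)
  expect_equal(c(ev$start, ev$end), c(0L, 1L))

  expect_equal(nrow(detect_interval_changes(c(0, 3, 5), 6)), 0L)

  ev2 <- detect_interval_changes(c(0, 10, 4, -1), 6)
  expect_equal(ev2$direction, c("expansion", "contraction"))
  expect_equal(ev2$magnitude, c(10, -11))

  expect_error(detect_interval_changes(c(0), 6), "at least 2")
  expect_error(detect_interval_changes(c(0, 8), 0), "> 0")
})

test_that("contraction status matches the spec's worked cases", {
  a <- classify_contraction_status(c(0, 10, 6, 2, 2), 6)
  expect_equal(a$status, "contracting")
  expect_equal(a$max_contraction, -8)

  b <- classify_contraction_status(c(0, 7, 14, 15), 6)
  expect_equal(b$status, "noncontracting")
  expect_true(b$expansion_only)

  # drop of 7 in a single month only: not sustained over >= 2 intervals
  cc <- classify_contraction_status(c(0, 10, 3, 9, 2), 6)
  expect_equal(cc$status, "noncontracting")
  expect_false(cc$expansion_only)
})

test_that("classifier agrees with the exhaustive window oracle on grid traces", {
  steps <- c(-7, -4, 0, 5, 8)
  set.seed(31)
  for (len in 3:8) {
    for (rep in 1:60) {
      pct <- cumsum(c(0, sample(steps, len - 1L, replace = TRUE)))
      got <- classify_contraction_status(pct, 6, 2L)$status
      expect_identical(got, contraction_oracle(pct, 6, 2L),
                       label = paste("trace", paste(pct, collapse = ",")))
    }
  }
})

test_that("raising the threshold never makes a subject contracting", {
  set.seed(77)
  for (rep in 1:200) {
    pct <- cumsum(c(0, rnorm(9, 0, 5)))
    lo <- classify_contraction_status(pct, 4)$status
    hi <- classify_contraction_status(pct, 8)$status
    expect_false(lo == "noncontracting" && hi == "contracting")
  }
})

test_that("coefficient of variation: examples and scale invariance", {
  expect_equal(coefficient_of_variation(c(10, 10, 10)), 0)
  expect_equal(coefficient_of_variation(c(9, 11)), 100 * sqrt(2) / 10,
               tolerance = 1e-6)
  x <- c(3, 9, 4, 7)
  expect_equal(coefficient_of_variation(x), coefficient_of_variation(13 * x))
  expect_error(coefficient_of_variation(c(-5, 5)), "zero mean")
  expect_error(coefficient_of_variation(3), "at least 2")
})

test_that("stratification partitions the cohort and counts events", {
  mk <- function(id, pcts) subject_series(
    id, "ms", seq_along(pcts) - 1L,
    list(ventricle_volume = 1000 * (1 + pcts / 100)))
  co <- vv_cohort(list(mk("s1", c(0, 10, 6, 2, 2)),
                       mk("s2", c(0, 7, 14, 15)),
                       mk("s3", c(0, 10, 3, 9, 2))))
  st <- stratify_cohort(co, 6)
  expect_equal(unname(st$group_sizes),
               c(1L, 2L))
  expect_equal(st$n_expansion_only, 1L)
  expect_equal(sum(st$group_sizes), nrow(st$table))
  expect_true(all(st$table$status %in% c("contracting", "noncontracting")))

  flat <- vv_cohort(list(mk("f1", rep(0, 5)), mk("f2", rep(0, 5))))
  sf <- stratify_cohort(flat, 6)
  expect_equal(unname(sf$group_sizes[["contracting"]]), 0L)
  expect_equal(sf$n_expansion_only, 0L)
  expect_equal(sf$prop_any_monthly_change, 0)
})

test_that("subjects with injected sustained falls are labelled contracting", {
  cfg <- ms_cohort_config(n_patients = 20, noise_sd = 0, atrophy_drift = 0,
                          episode_params = list(prob = 1,
                                                amp_range = c(0.15, 0.3),
                                                rise = c(1, 2), fall = c(2, 3)),
                          seed = 12)
  ms <- generate_ms_cohort(cfg)
  st <- stratify_cohort(ms, 6)
  gt <- attr(ms, "ground_truth")$episodes
  # every episode falls > 6% over >= 2 steps, so everyone is contracting
  falls <- gt[gt$end - gt$peak >= 2 & 100 * gt$amplitude > 6, "subject_id"]
  got <- st$table$status[match(falls, st$table$subject_id)]
  expect_true(all(got == "contracting"))
})

test_that("subjects with missing VV are excluded with a warning", {
  s1 <- subject_series("ok", "ms", 0:4,
                       list(ventricle_volume = c(100, 90, 85, 85, 84)))
  s2 <- subject_series("gap", "ms", 0:4,
                       list(ventricle_volume = c(100, NA, 85, 85, 84)))
  expect_warning(st <- stratify_cohort(vv_cohort(list(s1, s2)), 6),
                 "excluded.*gap")
  expect_equal(nrow(st$table), 1L)
  expect_equal(st$n_excluded, 1L)
})

test_that("cohort-level VV change reports both percent definitions", {
  mk <- function(id, v0, v1) subject_series(
    id, "ms", 0:1, list(ventricle_volume = c(v0, v1)))
  co <- vv_cohort(list(mk("a", 33000, 33300), mk("b", 33500, 33784),
                       mk("c", 34000, 34268)))
  ch <- cohort_vv_change(co)
  expect_equal(ch$median_baseline, 33500)
  expect_equal(ch$median_last, 33784)
  expect_equal(ch$median_difference, 284)
  expect_equal(ch$pct_of_median_baseline, 100 * 284 / 33500)
  expect_equal(ch$median_subject_pct_change,
               median(c(300 / 330, 284 / 335, 268 / 340)))
  expect_true(is.finite(ch$wilcoxon$p_value))
})
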