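test_that("screen enumerates the full subjects x variables x lags grid", {
  ms <- generate_ms_cohort(ms_cohort_config(n_patients = 5, seed = 3))
  sc <- run_ccf_screen(ms, max_lag = 2)
  expect_equal(sc$summary$total_coefficients, 5L * 12L * 5L)
  expect_equal(nrow(sc$records), 5L * 12L * 5L)
  expect_setequal(unique(sc$records$lag), -2:2)
  expect_equal(unique(sc$records$n_effective[sc$records$lag == 2]), 10)
  expect_true(all(abs(sc$records$coefficient) <= 1 + 1e-12, na.rm = TRUE))
})

test_that("records and summary are internally consistent", {
  ms <- generate_ms_cohort(ms_cohort_config(n_patients = 6, seed = 9))
  sc <- run_ccf_screen(ms)
  s <- sc$summary
  expect_lte(s$n_fdr_retained, s$n_nominal)
  expect_lte(s$n_nominal, s$total_coefficients)
  expect_equal(s$n_fdr_retained, sum(sc$records$significant))
  expect_equal(s$n_fdr_retained, sum(s$per_lag$n_retained))
  expect_equal(s$n_fdr_retained, sum(s$per_subject$n_retained))
  # q-values live in [0,1] and flags follow q <= alpha under pool = all
  q <- sc$records$q_fdr
  expect_true(all(q >= 0 & q <= 1, na.rm = TRUE))
  expect_equal(sc$records$significant,
               !is.na(q) & q <= sc$alpha)
})

test_that("an injected lag-1 coupling is recovered as the top record", {
  cfg <- ms_cohort_config(
    n_patients = 1, noise_sd = 0.002, atrophy_drift = 0,
    episode_params = list(prob = 1, amp_range = c(0.15, 0.25),
                          rise = c(2, 3), fall = c(2, 3)),
    couplings = list(coupling_spec("ventricle_volume", "t2_volume", 1, 0.9)),
    covariate_noise_sd = 0.05, seed = 21)
  ms <- generate_ms_cohort(cfg)
  sc <- run_ccf_screen(ms)
  top <- sc$records[which.max(abs(sc$records$coefficient)), ]
  expect_equal(top$y, "t2_volume")
  expect_equal(top$lag, 1L)
})

test_that("a long noise-free coupled series pins the CCF peak at the true lag", {
  cfg <- ms_cohort_config(
    n_patients = 1, n_timepoints = 200, noise_sd = 0.01, atrophy_drift = 0,
    episode_params = list(prob = 0, amp_range = c(0.1, 0.2),
                          rise = c(1, 2), fall = c(1, 2)),
    couplings = list(coupling_spec("ventricle_volume", "t2_volume", 1, 0.9)),
    covariate_noise_sd = 1e-6, seed = 4)
  ms <- generate_ms_cohort(cfg)
  x <- first_difference(ms[[1]]$variables$ventricle_volume)
  y <- first_difference(ms[[1]]$variables$t2_volume)
  cc <- cross_correlation(x, y, 2)
  expect_equal(cc$lag[which.max(abs(cc$coefficient))], 1L)
})

test_that("nominal-pool mode restricts the BH family to p < alpha", {
  ms <- generate_ms_cohort(ms_cohort_config(n_patients = 8, seed = 14))
  all_pool <- run_ccf_screen(ms, fdr_pool = "all")
  nom_pool <- run_ccf_screen(ms, fdr_pool = "nominal")
  expect_equal(all_pool$summary$n_nominal, nom_pool$summary$n_nominal)
  out_of_pool <- nom_pool$records$p_nominal >= nom_pool$alpha
  expect_true(all(is.na(nom_pool$records$q_fdr[out_of_pool])))
  # the nominal pool is smaller, so it can only retain more, never fewer
  expect_gte(nom_pool$summary$n_fdr_retained,
             all_pool$summary$n_fdr_retained)
})

test_that("subjects with incomplete series are skipped with a reason", {
  ms <- generate_ms_cohort(ms_cohort_config(n_patients = 3, seed = 5))
  gap <- ms[[2]]
  gap$variables$t2_volume[4] <- NA_real_
  broken <- vv_cohort(list(ms[[1]], gap, ms[[3]]))
  sc <- run_ccf_screen(broken)
  expect_equal(sc$skipped$subject_id, gap$subject_id)
  expect_match(sc$skipped$reason[1], "missing")
  expect_setequal(unique(sc$records$subject_id),
                  c(ms[[1]]$subject_id, ms[[3]]$subject_id))
  expect_equal(sc$summary$n_skipped, 1L)
})

test_that("degenerate constant series yield undefined records, excluded from FDR", {
  vars <- list(ventricle_volume = c(100, 101, 103, 102, 104, 103, 105, 104),
               flatvar = rep(5, 8),
               okvar = c(3, 1, 4, 1, 5, 9, 2, 6))
  s <- subject_series("deg", "ms", 0:7, vars)
  sc <- run_ccf_screen(vv_cohort(list(s)))
  flat_rec <- sc$records[sc$records$y == "flatvar", ]
  expect_true(all(is.na(flat_rec$coefficient)))
  expect_true(all(is.na(flat_rec$q_fdr)))
  expect_false(any(flat_rec$significant))
  expect_equal(sc$summary$n_undefined, nrow(flat_rec))
})

test_that("pure-noise cohorts rarely retain anything after FDR", {
  hits <- vapply(1:12, function(i) {
    sc <- run_ccf_screen(generate_null_cohort(seed = 1000 + i),
                         diagnostics = FALSE)
    sc$summary$n_fdr_retained
  }, 1L)
  expect_lte(sum(hits > 0), 2L)
})

test_that("summaries are permutation-invariant and count flags faithfully", {
  ms <- generate_ms_cohort(ms_cohort_config(n_patients = 6, seed = 2))
  sc <- run_ccf_screen(ms)
  shuffled <- sc$records[sample(nrow(sc$records)), ]
  s2 <- summarize_screen(shuffled, alpha = sc$alpha)
  expect_equal(s2$n_fdr_retained, sc$summary$n_fdr_retained)
  expect_equal(s2$n_nominal, sc$summary$n_nominal)
  expect_equal(s2$total_coefficients, sc$summary$total_coefficients)

  none <- sc$records
  none$significant <- FALSE
  s0 <- summarize_screen(none, alpha = sc$alpha)
  expect_equal(s0$n_fdr_retained, 0L)
  expect_equal(nrow(s0$lollipop), 0L)
})
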