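test_that("bootstrap of 58 identical subjects collapses to the point estimate", {
  # a single densely sampled subject (7 samples) cloned 58 times
  one <- simulate_study(seed = 111,
                        spec = cohort_spec(n_subjects = 1,
                                           samples_lambda = 20))
  rows <- lapply(1:58, function(j) {
    b <- tibble::as_tibble(one)
    b$id <- j
    b
  })
  ds <- as_pk_dataset(dplyr::bind_rows(rows))
  m <- pk_model(theta = c(cl = 2.45, v = 22.6), omega = c(cl = 0, v = 0),
                error = error_model("additive", sigma_add = 3))
  b <- bootstrap_pk(ds, m, n = 5, seed = 1)
  expect_identical(b$n_converged, 5L)
  # identical resamples: zero-width intervals, exactly
  expect_equal(b$summary$ci_high, b$summary$ci_low)
  # replicate refits agree with the base estimate to optimizer precision
  expect_equal(b$summary$median, b$summary$estimate, tolerance = 1e-4)
  expect_equal(b$summary$bias_percent, rep(0, nrow(b$summary)),
               tolerance = 1e-2)
})

test_that("bootstrap is reproducible under a seed and near-unbiased for tvcl", {
  ds <- simulate_study(n_subjects = 20, seed = 121)
  m <- pk_model(theta = c(cl = 2.45, v = 22.6),
                omega = c(cl = 0, v = 0.05),
                error = error_model("additive", sigma_add = 3.07))
  b1 <- bootstrap_pk(ds, m, n = 12, seed = 7)
  b2 <- bootstrap_pk(ds, m, n = 12, seed = 7)
  expect_identical(b1$summary, b2$summary)
  expect_identical(b1$estimates, b2$estimates)
  tv <- dplyr::filter(b1$summary, term == "tvcl")
  expect_lt(abs(tv$bias_percent), 15)
  expect_true(tv$ci_low <= tv$median && tv$median <= tv$ci_high)
})

test_that("VPC is seed-reproducible and collapses without variability", {
  ds <- simulate_study(n_subjects = 20, seed = 131)
  fit0 <- fit_foce(ds, final_model,
                   fix = c("tvcl", "tvv", "b_cl_crcl", "b_cl_wt",
                           "om2_cl", "om2_v", "sig_add"),
                   control = fast_ctl)
  v1 <- vpc_pk(fit0, n_sim = 40, seed = 5)
  v2 <- vpc_pk(fit0, n_sim = 40, seed = 5)
  expect_identical(v1$bands, v2$bands)
  expect_true(all(v1$bands$pi_low <= v1$bands$pi_high))

  # no BSV, (near) no residual error: all percentiles sit on the typical curve
  m0 <- pk_model(theta = c(cl = 2.45, v = 22.6),
                 relations = final_model$relations,
                 omega = c(cl = 0, v = 0),
                 error = error_model("additive", sigma_add = 1e-9))
  ds0 <- simulate_study(n_subjects = 15, model = m0, seed = 132)
  fitd <- fit_foce(ds0, m0, fix = c("tvcl", "tvv", "b_cl_crcl", "b_cl_wt",
                                    "sig_add"),
                   control = fast_ctl)
  v0 <- vpc_pk(fitd, n_sim = 25, seed = 6)
  expect_equal(v0$bands$pi_low, v0$bands$pi_high, tolerance = 1e-6)
  expect_equal(v0$bands$observed, v0$bands$sim_median, tolerance = 1e-6)
})

test_that("VPC bands widen with between-subject variability", {
  m_lo <- pk_model(theta = c(cl = 2.45, v = 22.6),
                   omega = c(cl = 0.01, v = 0.01),
                   error = error_model("additive", sigma_add = 1))
  m_hi <- pk_model(theta = c(cl = 2.45, v = 22.6),
                   omega = c(cl = 0.16, v = 0.16),
                   error = error_model("additive", sigma_add = 1))
  ds <- simulate_study(n_subjects = 30, model = m_lo, seed = 141)
  fit_lo <- fit_foce(ds, m_lo, fix = c("tvcl", "tvv", "om2_cl", "om2_v",
                                       "sig_add"), control = fast_ctl)
  fit_hi <- fit_foce(ds, m_hi, fix = c("tvcl", "tvv", "om2_cl", "om2_v",
                                       "sig_add"), control = fast_ctl)
  v_lo <- vpc_pk(fit_lo, n_sim = 60, bins = 4, seed = 8)
  v_hi <- vpc_pk(fit_hi, n_sim = 60, bins = 4, seed = 8)
  w_lo <- v_lo$bands$pi_high - v_lo$bands$pi_low
  w_hi <- v_hi$bands$pi_high - v_hi$bands$pi_low
  expect_true(all(w_hi > w_lo))
})

test_that("GOF table has one row per observation with consistent columns", {
  ds <- simulate_study(n_subjects = 20, seed = 151)
  fit <- fit_foce(ds, final_model, control = fast_ctl)
  g <- gof_tables(fit)
  expect_identical(nrow(g), sum(ds$evid == 0))
  expect_named(g, c("id", "time", "tad", "dv", "pred", "ipred", "cwres"))
  expect_identical(g$cwres, compute_cwres(fit)$cwres)
  expect_true(all(g$tad >= 0 & g$tad <= g$time))

  # perfect fit: simulated without noise at fixed parameters
  m0 <- pk_model(theta = c(cl = 2.45, v = 22.6), omega = c(cl = 0, v = 0),
                 error = error_model("additive", sigma_add = 1e-12))
  ds0 <- simulate_study(n_subjects = 6, model = m0, seed = 152)
  m_eval <- pk_model(theta = c(cl = 2.45, v = 22.6), omega = c(cl = 0, v = 0),
                     error = error_model("additive", sigma_add = 1))
  fit0 <- fit_foce(ds0, m_eval, fix = c("tvcl", "tvv", "sig_add"),
                   control = fast_ctl)
  g0 <- gof_tables(fit0)
  expect_equal(g0$dv, g0$pred, tolerance = 1e-8)
  expect_equal(g0$dv, g0$ipred, tolerance = 1e-8)
})

test_that("simulate_dataset preserves the design and responds to the seed", {
  ds <- simulate_study(n_subjects = 10, seed = 161)
  s1 <- simulate_dataset(ds, final_model, seed = 9)
  s2 <- simulate_dataset(ds, final_model, seed = 9)
  s3 <- simulate_dataset(ds, final_model, seed = 10)
  expect_identical(s1$dv, s2$dv)
  expect_false(identical(s1$dv, s3$dv))
  expect_identical(s1$time, ds$time)
  expect_identical(s1$amt, ds$amt)
  expect_identical(s1$dv[s1$evid == 1], ds$dv[ds$evid == 1])
  expect_true(all(s1$dv[s1$evid == 0] >= 0))
})
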