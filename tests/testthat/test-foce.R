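test_that("with Omega = 0 the objective reduces to weighted least squares form", {
  ds <- make_dataset(list(c(1, 4, 8), c(2, 6)), dv = list(c(30, 20, 12),
                                                          c(25, 15)))
  m <- pk_model(theta = c(cl = 2.45, v = 22.6), omega = c(cl = 0, v = 0),
                error = error_model("additive", sigma_add = 3))
  prep <- vancopk:::foce_prep(ds)
  got <- vancopk:::foce_eval(prep, m, engine = "cpp")$ofv
  # direct evaluation of sum[(y - f(0))^2 / g + log g]
  f <- unlist(lapply(1:2, function(i) {
    conc_one_cmt(prep$t[prep$obs_start[i] + seq_len(prep$obs_len[i])],
                 2.45, 22.6, pk_dose(0, 1000, 0.5))
  }))
  want <- sum((prep$y - f)^2 / 9 + log(9))
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("FOCE-I agrees with quadrature on a two-subject toy problem", {
  m <- pk_model(theta = c(cl = 2.45, v = 22.6),
                omega = c(cl = 0.0128, v = 0.052),
                error = error_model("additive", sigma_add = 3.07))
  ds <- simulate_study(n_subjects = 2, model = m, seed = 21)
  prep <- vancopk:::foce_prep(ds)
  foce <- vancopk:::foce_eval(prep, m, engine = "cpp")$ofv
  oracle <- quad_ofv(ds, m)
  expect_lt(abs(foce - oracle), 0.5)
})

test_that("FOCE-I tracks the quadrature oracle across random models", {
  set.seed(314)
  worst <- 0
  for (rep in 1:20) {
    m <- pk_model(
      theta = c(cl = runif(1, 1.5, 4), v = runif(1, 15, 35)),
      omega = c(cl = runif(1, 0.01, 0.05), v = runif(1, 0.01, 0.05)),
      error = error_model("additive", sigma_add = runif(1, 1, 4))
    )
    n_subj <- sample(1:3, 1)
    spec <- cohort_spec(n_subjects = n_subj, samples_lambda = 3,
                        sample_grid = c(0.5, 2, 6, 12))
    ds <- simulate_study(model = m, seed = 1000 + rep, spec = spec)
    prep <- vancopk:::foce_prep(ds)
    foce <- vancopk:::foce_eval(prep, m, engine = "cpp")$ofv
    oracle <- quad_ofv(ds, m)
    worst <- max(worst, abs(foce - oracle))
  }
  expect_lt(worst, 1)
})

test_that("compiled and reference R engines agree", {
  ds <- simulate_study(n_subjects = 20, seed = 31)
  prep <- vancopk:::foce_prep(ds)
  a <- vancopk:::foce_eval(prep, final_model, detail = TRUE, engine = "cpp")
  b <- vancopk:::foce_eval(prep, final_model, detail = TRUE, engine = "r")
  expect_equal(a$ofv, b$ofv, tolerance = 1e-6)
  expect_equal(a$ipred, b$ipred, tolerance = 1e-4)
  expect_equal(a$cwres, b$cwres, tolerance = 1e-3)
  expect_equal(a$pred, b$pred, tolerance = 1e-8)
})

test_that("noiseless data with Omega = 0 identify theta exactly", {
  m_true <- pk_model(theta = c(cl = 2.45, v = 22.6), omega = c(cl = 0, v = 0),
                     error = error_model("additive", sigma_add = 1e-12))
  ds <- simulate_study(n_subjects = 10, model = m_true, seed = 41)
  m_init <- pk_model(theta = c(cl = 4, v = 35), omega = c(cl = 0, v = 0),
                     error = error_model("additive", sigma_add = 0.1))
  fit <- fit_foce(ds, m_init, fix = "sig_add", control = fast_ctl)
  est <- setNames(fit$params$estimate, fit$params$term)
  expect_equal(unname(est["tvcl"]), 2.45, tolerance = 1e-4)
  expect_equal(unname(est["tvv"]), 22.6, tolerance = 1e-4)
})

test_that("fitting is deterministic: same data and init give the same OFV", {
  ds <- simulate_study(n_subjects = 10, seed = 51)
  f1 <- fit_foce(ds, final_model, control = fast_ctl)
  f2 <- fit_foce(ds, final_model, control = fast_ctl)
  expect_identical(f1$ofv, f2$ofv)
  expect_identical(f1$params$estimate, f2$params$estimate)
})

test_that("with Omega = 0 and additive error the fit is nonlinear least squares", {
  m_true <- pk_model(theta = c(cl = 2.45, v = 22.6), omega = c(cl = 0, v = 0),
                     error = error_model("additive", sigma_add = 2))
  ds <- simulate_study(n_subjects = 15, model = m_true, seed = 61)
  fit <- fit_foce(ds, m_true, control = fast_ctl)
  est <- setNames(fit$params$estimate, fit$params$term)
  # independent route: minimize the residual sum of squares directly
  prep <- vancopk:::foce_prep(ds)
  ssr <- function(lp) {
    p <- exp(lp)  # log scale keeps the search in the positive orthant
    tot <- 0
    for (i in seq_len(prep$n_subj)) {
      osel <- prep$obs_start[i] + seq_len(prep$obs_len[i])
      dsel <- prep$dose_start[i] + seq_len(prep$dose_len[i])
      f <- conc_one_cmt(prep$t[osel], p[1], p[2],
                        tibble::tibble(start_time = prep$d_t0[dsel],
                                       amount = prep$d_amt[dsel],
                                       duration = prep$d_dur[dsel]))
      tot <- tot + sum((prep$y[osel] - f)^2)
    }
    tot
  }
  ols <- stats::optim(log(c(2.45, 22.6)), ssr, method = "BFGS",
                      control = list(reltol = 1e-12))
  expect_equal(unname(est["tvcl"]), exp(ols$par[1]), tolerance = 1e-3)
  expect_equal(unname(est["tvv"]), exp(ols$par[2]), tolerance = 1e-3)
  # and sigma-hat^2 equals the mean squared residual at the optimum
  expect_equal(unname(est["sig_add"])^2, ols$value / length(prep$y),
               tolerance = 1e-2)
})

test_that("CWRES vanish for a perfect fit and center near zero otherwise", {
  m_true <- pk_model(theta = c(cl = 2.45, v = 22.6), omega = c(cl = 0, v = 0),
                     error = error_model("additive", sigma_add = 1e-12))
  ds <- simulate_study(n_subjects = 8, model = m_true, seed = 71)
  m_eval <- pk_model(theta = c(cl = 2.45, v = 22.6), omega = c(cl = 0, v = 0),
                     error = error_model("additive", sigma_add = 1))
  fit <- fit_foce(ds, m_eval,
                  fix = c("tvcl", "tvv", "sig_add"), control = fast_ctl)
  expect_true(all(abs(fit$residuals$cwres) < 1e-6))
  expect_equal(fit$residuals$dv, fit$residuals$pred, tolerance = 1e-6)
  expect_equal(fit$residuals$ipred, fit$residuals$pred, tolerance = 1e-6)

  big <- simulate_study(n_subjects = 150, model = final_model, seed = 72)
  fitb <- fit_foce(big, final_model,
                   fix = c("tvcl", "tvv", "b_cl_crcl", "b_cl_wt",
                           "om2_cl", "om2_v", "sig_add"),
                   control = fast_ctl)
  expect_lt(abs(mean(fitb$residuals$cwres)), 0.1)
  expect_identical(compute_cwres(fitb)$cwres, fitb$residuals$cwres)
})

test_that("standard errors come back finite for an identifiable model", {
  ds <- simulate_study(n_subjects = 25, seed = 81)
  m <- pk_model(theta = c(cl = 2.45, v = 22.6),
                omega = c(cl = 0, v = 0.05),
                error = error_model("additive", sigma_add = 3.07))
  fit <- fit_foce(ds, m)
  p <- fit$params
  expect_true(all(is.finite(p$rse[p$term %in% c("tvcl", "tvv")])))
  expect_true(all(p$rse[p$term %in% c("tvcl", "tvv")] > 0))
  expect_s3_class(glance(fit), "tbl_df")
  expect_identical(augment(fit), fit$residuals)
})
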