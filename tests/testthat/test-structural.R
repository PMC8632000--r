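test_that("single-infusion concentration matches the closed form", {
  d <- pk_dose(0, 1000, 0.5)
  k <- 2.45 / 22.6
  expect_equal(conc_one_cmt(0.5, 2.45, 22.6, d),
               (2000 / 2.45) * (1 - exp(-k * 0.5)))
  expect_equal(round(conc_one_cmt(0.5, 2.45, 22.6, d), 2), 43.07)
  # post-infusion decay of the end-of-infusion concentration
  expect_equal(conc_one_cmt(3, 2.45, 22.6, d),
               conc_one_cmt(0.5, 2.45, 22.6, d) * exp(-k * 2.5))
})

test_that("no doses means no drug, and times before dosing are zero", {
  expect_equal(conc_one_cmt(c(0, 1, 5), 2, 20, pk_dose(0, 100, 0.5)[0, ]),
               c(0, 0, 0))
  expect_equal(conc_one_cmt(1, 2, 20, pk_dose(2, 100, 0.5)), 0)
})

test_that("concentration is linear in dose and continuous at infusion end", {
  tgrid <- c(0.1, 0.5, 1, 3, 7, 12, 25)
  d1 <- pk_dose(c(0, 12), c(500, 500), 0.5)
  d2 <- pk_dose(c(0, 12), c(1000, 1000), 0.5)
  expect_equal(conc_one_cmt(tgrid, 2.45, 22.6, d2),
               2 * conc_one_cmt(tgrid, 2.45, 22.6, d1))
  eps <- 1e-9
  expect_equal(conc_one_cmt(0.5 - eps, 2.45, 22.6, d1),
               conc_one_cmt(0.5 + eps, 2.45, 22.6, d1), tolerance = 1e-6)
  expect_true(all(conc_one_cmt(tgrid, 2.45, 22.6, d1) >= 0))
})

test_that("steady-state trough equals 30-dose superposition within 0.1%", {
  cl <- 1.5354
  v <- 22.6
  tr <- ss_trough_one_cmt(1000, 12, 0.5, cl, v)
  expect_equal(round(tr, 1), 35.7)
  # independent oracle: explicit superposition of 30 q12h doses
  doses <- pk_dose(seq(0, by = 12, length.out = 30), 1000, 0.5)
  sup <- conc_one_cmt(30 * 12, cl, v, doses)
  expect_equal(tr, sup, tolerance = 1e-3)
  # and for a second parameter set with a short half-life
  tr2 <- ss_trough_one_cmt(500, 8, 1, 6, 30)
  sup2 <- conc_one_cmt(30 * 8, 6, 30, pk_dose(seq(0, by = 8, length.out = 30),
                                              500, 1))
  expect_equal(tr2, sup2, tolerance = 1e-3)
})

test_that("trough is exactly linear in dose and validates its domain", {
  expect_equal(ss_trough_one_cmt(400, 12, 0.5, 2.4, 22) /
                 ss_trough_one_cmt(1000, 12, 0.5, 2.4, 22), 0.4)
  expect_equal(ss_trough_one_cmt(0, 12, 0.5, 2.4, 22), 0)
  expect_error(ss_trough_one_cmt(1000, 0.5, 0.5, 2.4, 22), "tau > t_inf")
  # monotone: increasing in dose, decreasing in cl
  expect_true(ss_trough_one_cmt(1200, 12, 0.5, 2.4, 22) >
                ss_trough_one_cmt(1000, 12, 0.5, 2.4, 22))
  expect_true(ss_trough_one_cmt(1000, 12, 0.5, 3.0, 22) <
                ss_trough_one_cmt(1000, 12, 0.5, 2.4, 22))
})

test_that("steady-state AUC over one interval equals dose/cl (mass balance)", {
  cl <- 2.45
  v <- 22.6
  doses <- pk_dose(seq(0, by = 12, length.out = 40), 1000, 0.5)
  auc <- stats::integrate(function(t) conc_one_cmt(t, cl, v, doses),
                          39 * 12, 40 * 12, rel.tol = 1e-9,
                          subdivisions = 500)$value
  expect_equal(auc, 1000 / cl, tolerance = 1e-3)
})

test_that("two-compartment model collapses to one compartment as q -> 0", {
  tgrid <- c(0.25, 0.5, 2, 6, 12)
  d <- pk_dose(0, 1000, 0.5)
  c1 <- conc_one_cmt(tgrid, 2.45, 22.6, d)
  c2 <- conc_two_cmt(tgrid, 2.45, 22.6, q = 1e-7, v2 = 10, d)
  expect_equal(c2, c1, tolerance = 1e-6)
  expect_equal(conc_two_cmt(tgrid, 2, 20, 1, 10, d[0, ]), rep(0, 5))
  expect_error(conc_two_cmt(1, 2, 20, NA, 10, d), "q")
})

test_that("two-compartment closed form agrees with ODE integration", {
  skip_if_not_installed("deSolve")
  set.seed(99)
  cl <- runif(1, 1, 5); v <- runif(1, 10, 40)
  q <- runif(1, 0.5, 8); v2 <- runif(1, 5, 60)
  d <- pk_dose(c(0, 12), c(1000, 750), c(0.5, 1))
  rhs <- function(t, y, p) {
    rate <- sum(d$amount / d$duration *
                  (t >= d$start_time & t < d$start_time + d$duration))
    dA1 <- rate - (cl / v) * y[1] - (q / v) * y[1] + (q / v2) * y[2]
    dA2 <- (q / v) * y[1] - (q / v2) * y[2]
    list(c(dA1, dA2))
  }
  tout <- c(0, 0.25, 0.5, 1, 3, 6, 12, 12.5, 13, 18, 24)
  num <- deSolve::lsoda(c(0, 0), tout, rhs, NULL, rtol = 1e-10, atol = 1e-10)
  ode_conc <- num[, 2] / v
  ana <- conc_two_cmt(tout, cl, v, q, v2, d)
  expect_equal(ana[-1], ode_conc[-1], tolerance = 1e-6)
})

test_that("concentrations are non-negative across random parameter draws", {
  set.seed(17)
  for (rep in 1:25) {
    cl <- runif(1, 0.5, 8); v <- runif(1, 5, 60)
    d <- pk_dose(sort(runif(3, 0, 24)), runif(3, 100, 1500),
                 runif(3, 0.25, 2))
    tt <- sort(runif(20, 0, 48))
    expect_true(all(conc_one_cmt(tt, cl, v, d) >= 0))
  }
})
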