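# Shared fixtures and independent oracles for the test suite.

# Build a small event dataset in code: one subject per element of
# `obs_times`, each receiving a single infusion at time 0.
make_dataset <- function(obs_times, dv, dose = 1000, t_inf = 0.5,
                         age = 54, wt = 75, sex = "male", scr = 0.935,
                         crcl = NULL) {
  n <- length(obs_times)
  age <- rep_len(age, n); wt <- rep_len(wt, n)
  sex <- rep_len(sex, n); scr <- rep_len(scr, n)
  dose <- rep_len(dose, n)
  rows <- lapply(seq_len(n), function(i) {
    tt <- obs_times[[i]]
    tibble::tibble(
      id = i,
      time = c(0, tt),
      evid = c(1L, rep(0L, length(tt))),
      amt = c(dose[i], rep(NA_real_, length(tt))),
      rate = c(dose[i] / t_inf, rep(NA_real_, length(tt))),
      dv = c(NA_real_, dv[[i]]),
      mdv = c(1L, rep(0L, length(tt))),
      age = age[i], wt = wt[i], sex = sex[i], scr = scr[i]
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(crcl)) out$crcl <- rep(rep_len(crcl, n), lengths(obs_times) + 1)
  as_pk_dataset(out)
}

# Independent -2 log marginal likelihood by dense trapezoid quadrature
# over the random effects (1D or 2D depending on which variances are
# positive), minus the n*log(2*pi) constant so it is directly comparable
# with the engines' OFV.
quad_ofv <- function(data, model, npt = 101, width = 5) {
  prep <- vancopk:::foce_prep(data)
  tp <- vancopk:::typical_params(prep$covs, model$theta, model$relations)
  s2 <- vancopk:::sigma_variances(model$error)
  om <- model$omega
  total <- 0
  ntot <- 0
  for (i in seq_len(prep$n_subj)) {
    osel <- prep$obs_start[i] + seq_len(prep$obs_len[i])
    dsel <- prep$dose_start[i] + seq_len(prep$dose_len[i])
    y <- prep$y[osel]
    tt <- prep$t[osel]
    ntot <- ntot + length(y)
    doses <- tibble::tibble(start_time = prep$d_t0[dsel],
                            amount = prep$d_amt[dsel],
                            duration = prep$d_dur[dsel])
    loglik <- function(e1, e2) {
      f <- conc_one_cmt(tt, tp$cl[i] * exp(e1), tp$v[i] * exp(e2), doses)
      g <- s2$add + s2$prop * pmax(f, 0.01)^2
      sum(dnorm(y, f, sqrt(g), log = TRUE))
    }
    grid1 <- function(om2) {
      s <- sqrt(om2)
      seq(-width * s, width * s, length.out = npt)
    }
    if (om[["cl"]] > 0 && om[["v"]] > 0) {
      e1 <- grid1(om[["cl"]]); e2 <- grid1(om[["v"]])
      lg <- outer(seq_along(e1), seq_along(e2), Vectorize(function(a, b) {
        loglik(e1[a], e2[b]) +
          dnorm(e1[a], 0, sqrt(om[["cl"]]), log = TRUE) +
          dnorm(e2[b], 0, sqrt(om[["v"]]), log = TRUE)
      }))
      w1 <- diff(e1)[1]; w2 <- diff(e2)[1]
      m <- max(lg)
      li <- log(sum(exp(lg - m)) * w1 * w2) + m
    } else if (om[["cl"]] > 0 || om[["v"]] > 0) {
      on_cl <- om[["cl"]] > 0
      om2 <- if (on_cl) om[["cl"]] else om[["v"]]
      e <- grid1(om2)
      lg <- vapply(e, function(x) {
        (if (on_cl) loglik(x, 0) else loglik(0, x)) +
          dnorm(x, 0, sqrt(om2), log = TRUE)
      }, numeric(1))
      m <- max(lg)
      li <- log(sum(exp(lg - m)) * diff(e)[1]) + m
    } else {
      li <- loglik(0, 0)
    }
    total <- total - 2 * li
  }
  total - ntot * log(2 * pi)
}

# the reported final-model parameters, used all over the suite
final_model <- vanco_final_model()

# a fast control for repeated fitting in simulations
fast_ctl <- foce_control(hessian = FALSE)
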