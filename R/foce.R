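#' Control settings for FOCE-I estimation
#'
#' @param maxit Maximum outer iterations.
#' @param rel_tol Relative convergence tolerance on the objective
#'   function value.
#' @param inner_tol Convergence tolerance of the inner (eta) search used
#'   by the reference R engine.
#' @param engine `"auto"` (compiled engine for the one-compartment model,
#'   R engine otherwise), `"cpp"`, or `"r"`.
#' @param hessian Compute standard errors from a finite-difference
#'   Hessian of the objective function.
#' @return A list of class `foce_control`.
#' @export
foce_control <- function(maxit = 500, rel_tol = 1e-8, inner_tol = 1e-8,
                         engine = c("auto", "cpp", "r"), hessian = TRUE) {
  structure(list(maxit = maxit, rel_tol = rel_tol, inner_tol = inner_tol,
                 engine = match.arg(engine), hessian = hessian),
            class = "foce_control")
}

# ---- data preparation -------------------------------------------------

# flatten a pk_dataset into per-subject index ranges for the engines
foce_prep <- function(data) {
  data <- as_pk_dataset(data)
  ids <- unique(data$id)
  obs <- data[data$evid == 0, ]
  dose <- data[data$evid == 1, ]
  obs_split <- split(seq_len(nrow(obs)), factor(obs$id, levels = ids))
  dose_split <- split(seq_len(nrow(dose)), factor(dose$id, levels = ids))
  n_obs <- lengths(obs_split)
  n_dose <- lengths(dose_split)
  if (any(n_obs == 0) || any(n_dose == 0)) {
    abort("Every subject needs at least one dose and one observation.")
  }
  # reorder flat arrays so each subject's rows are contiguous
  oidx <- unlist(obs_split, use.names = FALSE)
  didx <- unlist(dose_split, use.names = FALSE)
  obs <- obs[oidx, ]
  dose <- dose[didx, ]
  # time after most recent dose start, for GOF tables
  tad <- obs$time
  for (i in seq_along(ids)) {
    sel <- obs$id == ids[i]
    dts <- dose$time[dose$id == ids[i]]
    tad[sel] <- vapply(obs$time[sel], function(t) {
      prev <- dts[dts <= t]
      if (length(prev)) t - max(prev) else t
    }, numeric(1))
  }
  covs <- dplyr::distinct(dplyr::select(
    tibble::as_tibble(data),
    dplyr::all_of(c("id", "age", "wt", "sex", "scr", "crcl"))), .data$id,
    .keep_all = TRUE)
  covs <- covs[match(ids, covs$id), ]
  list(
    ids = ids, n_subj = length(ids),
    y = obs$dv, t = obs$time, obs_id = obs$id, tad = tad,
    obs_start = cumsum(c(0L, unname(n_obs[-length(n_obs)]))),
    obs_len = unname(n_obs),
    d_t0 = dose$time, d_amt = dose$amt, d_dur = dose$amt / dose$rate,
    dose_start = cumsum(c(0L, unname(n_dose[-length(n_dose)]))),
    dose_len = unname(n_dose),
    covs = covs
  )
}

# ---- parameter packing ------------------------------------------------

# one row per model parameter; slopes of allometric relations are fixed
# exponents and never estimated
foce_param_table <- function(model) {
  pt <- tibble::tibble(
    term = c("tvcl", "tvv"),
    init = c(model$theta[["cl"]], model$theta[["v"]]),
    transform = "log", kind = "theta", index = NA_integer_
  )
  if (model$structural == "two_cmt") {
    pt <- dplyr::bind_rows(pt, tibble::tibble(
      term = c("tvq", "tvv2"),
      init = c(model$theta[["q"]], model$theta[["v2"]]),
      transform = "log", kind = "theta", index = NA_integer_
    ))
  }
  rel <- model$relations
  if (!is.null(rel) && nrow(rel)) {
    for (i in seq_len(nrow(rel))) {
      if (rel$form[i] == "power_allometric") next
      pt <- dplyr::bind_rows(pt, tibble::tibble(
        term = paste0("b_", rel$parameter[i], "_", rel$covariate[i]),
        init = rel$value[i], transform = "identity", kind = "slope",
        index = i
      ))
    }
  }
  pt <- dplyr::bind_rows(pt, tibble::tibble(
    term = c("om2_cl", "om2_v"),
    init = unname(model$omega[c("cl", "v")]),
    transform = "log", kind = "omega", index = NA_integer_
  ))
  if (!is.null(model$error$sigma_add)) {
    pt <- dplyr::bind_rows(pt, tibble::tibble(
      term = "sig_add", init = model$error$sigma_add, transform = "log",
      kind = "sigma", index = NA_integer_
    ))
  }
  if (!is.null(model$error$sigma_prop)) {
    pt <- dplyr::bind_rows(pt, tibble::tibble(
      term = "sig_prop", init = model$error$sigma_prop, transform = "log",
      kind = "sigma", index = NA_integer_
    ))
  }
  pt
}

par_fwd <- function(x, transform) {
  x[transform == "log"] <- log(x[transform == "log"])
  x
}
par_bwd <- function(x, transform) {
  x[transform == "log"] <- exp(x[transform == "log"])
  x
}

# rebuild a pk_model carrying a full parameter vector
model_with_params <- function(model, full) {
  theta <- model$theta
  theta[["cl"]] <- full[["tvcl"]]
  theta[["v"]] <- full[["tvv"]]
  if (model$structural == "two_cmt") {
    theta[["q"]] <- full[["tvq"]]
    theta[["v2"]] <- full[["tvv2"]]
  }
  rel <- model$relations
  if (!is.null(rel) && nrow(rel)) {
    for (i in seq_len(nrow(rel))) {
      nm <- paste0("b_", rel$parameter[i], "_", rel$covariate[i])
      if (nm %in% names(full)) rel$value[i] <- full[[nm]]
    }
  }
  omega <- c(cl = unname(full[["om2_cl"]]), v = unname(full[["om2_v"]]))
  err <- model$error
  if ("sig_add" %in% names(full)) err$sigma_add <- unname(full[["sig_add"]])
  if ("sig_prop" %in% names(full)) err$sigma_prop <- unname(full[["sig_prop"]])
  m <- model
  m$theta <- theta
  m$relations <- rel
  m$omega <- omega
  m$error <- err
  m
}

# ---- engines ----------------------------------------------------------

sigma_variances <- function(error) {
  list(add = if (is.null(error$sigma_add)) 0 else error$sigma_add^2,
       prop = if (is.null(error$sigma_prop)) 0 else error$sigma_prop^2)
}

foce_eval <- function(prep, model, detail = FALSE, engine = "cpp",
                      inner_tol = 1e-8) {
  tp <- typical_params(prep$covs, model$theta, model$relations,
                       warn_floor = FALSE)
  s2 <- sigma_variances(model$error)
  if (engine == "cpp" && model$structural == "one_cmt") {
    foce_engine_cpp(
      as.integer(prep$obs_start), as.integer(prep$obs_len),
      prep$y, prep$t,
      as.integer(prep$dose_start), as.integer(prep$dose_len),
      prep$d_t0, prep$d_amt, prep$d_dur,
      tp$cl, tp$v,
      model$omega[["cl"]], model$omega[["v"]], s2$add, s2$prop,
      detail
    )
  } else {
    foce_engine_r(prep, tp$cl, tp$v, model, s2, detail, inner_tol)
  }
}

# Reference R implementation of the FOCE-I objective. Slower than the
# compiled engine but structural-model agnostic; also the production path
# for the two-compartment model.
foce_engine_r <- function(prep, clt, vt, model, s2, detail = FALSE,
                          inner_tol = 1e-8) {
  om2 <- model$omega
  e1 <- om2[["cl"]] > 0
  e2 <- om2[["v"]] > 0
  conc_fun <- function(tt, cl, v, doses) {
    if (model$structural == "one_cmt") {
      conc_one_cmt(tt, cl, v, doses)
    } else {
      conc_two_cmt(tt, cl, v, model$theta[["q"]], model$theta[["v2"]], doses)
    }
  }
  ofv <- 0
  ns <- prep$n_subj
  ntot <- length(prep$y)
  eta_out <- matrix(0, ns, 2)
  pred_out <- ipred_out <- cwres_out <- numeric(ntot)
  sofv_out <- numeric(ns)
  for (i in seq_len(ns)) {
    osel <- prep$obs_start[i] + seq_len(prep$obs_len[i])
    dsel <- prep$dose_start[i] + seq_len(prep$dose_len[i])
    y <- prep$y[osel]
    tt <- prep$t[osel]
    doses <- tibble::tibble(start_time = prep$d_t0[dsel],
                            amount = prep$d_amt[dsel],
                            duration = prep$d_dur[dsel])
    fpred <- function(eta) {
      conc_fun(tt, clt[i] * exp(eta[1]), vt[i] * exp(eta[2]), doses)
    }
    gvar <- function(f) s2$add + s2$prop * pmax(f, 0.01)^2
    hobj <- function(eta) {
      f <- fpred(eta)
      g <- gvar(f)
      h <- sum((y - f)^2 / g + log(g))
      if (e1) h <- h + eta[1]^2 / om2[["cl"]]
      if (e2) h <- h + eta[2]^2 / om2[["v"]]
      h
    }
    eta <- c(0, 0)
    if (e1 || e2) {
      free <- c(e1, e2)
      fit <- nlminb(numeric(sum(free)), function(ef) {
        eta_full <- c(0, 0)
        eta_full[free] <- ef
        hobj(eta_full)
      }, control = list(rel.tol = inner_tol))
      eta[free] <- fit$par
    }
    f <- fpred(eta)
    hstep <- 1e-4
    G <- matrix(0, length(y), 2)
    for (j in 1:2) {
      if ((j == 1 && !e1) || (j == 2 && !e2)) next
      ep <- em <- eta
      ep[j] <- ep[j] + hstep
      em[j] <- em[j] - hstep
      G[, j] <- (fpred(ep) - fpred(em)) / (2 * hstep)
    }
    g <- gvar(f)
    V <- diag(g, nrow = length(g))
    if (e1) V <- V + om2[["cl"]] * tcrossprod(G[, 1])
    if (e2) V <- V + om2[["v"]] * tcrossprod(G[, 2])
    r <- y - f + as.numeric(G %*% eta)
    L <- tryCatch(t(chol(V)), error = function(e) NULL)
    if (is.null(L)) {
      diag(V) <- diag(V) + 1e-8 * (1 + max(diag(V)))
      L <- tryCatch(t(chol(V)), error = function(e) {
        abort(paste0("FOCE covariance matrix not positive definite for ",
                     "subject ", prep$ids[i], "."))
      })
    }
    u <- forwardsolve(L, r)
    ofv_i <- 2 * sum(log(diag(L))) + sum(u^2)
    ofv <- ofv + ofv_i
    if (detail) {
      eta_out[i, ] <- eta
      sofv_out[i] <- ofv_i
      pred_out[osel] <- conc_fun(tt, clt[i], vt[i], doses)
      ipred_out[osel] <- f
      cwres_out[osel] <- u
    }
  }
  if (!detail) return(list(ofv = ofv, inner_ok = TRUE))
  list(ofv = ofv, inner_ok = TRUE, eta = eta_out, subject_ofv = sofv_out,
       pred = pred_out, ipred = ipred_out, cwres = cwres_out)
}

# ---- fitting ----------------------------------------------------------

#' Fit a population PK model by FOCE-I
#'
#' Estimates the typical values, covariate slopes, between-subject
#' variances, and residual-error parameters of a [pk_model()] by
#' minimizing the first-order conditional (with interaction) approximation
#' to -2 log-likelihood. Typical values, variances and error SDs are
#' optimized on the log scale; covariate slopes on the identity scale.
#' The `n log(2*pi)` constant is omitted from the objective, following the
#' usual OFV reporting convention. The fit is deterministic: no random
#' numbers are used and the inner eta search always starts from zero.
#'
#' @param data A `pk_dataset` (or coercible data frame).
#' @param model A [pk_model()] whose parameter values serve as initial
#'   estimates.
#' @param init Optional named numeric vector overriding initial values
#'   (names as in the `term` column of [tidy()] output, e.g. `tvcl`,
#'   `b_cl_crcl`, `om2_cl`, `sig_add`).
#' @param fix Character vector of parameter names to hold fixed at their
#'   initial values. Variances initialized at 0 are always fixed (the
#'   corresponding random effect is disabled).
#' @param control A [foce_control()].
#' @return An object of class `pk_fit` with components `ofv`, `params`
#'   (estimates, SEs, RSEs), `model_fit` (the model carrying the
#'   estimates), `ebes` (empirical Bayes eta estimates), `residuals`
#'   (PRED/IPRED/CWRES per observation), `converged`, and `boundary`.
#'   Methods: [tidy()], [glance()], [augment()], [autoplot][gof_plot].
#' @export
#' @examples
#' ds <- simulate_study(n_subjects = 12, seed = 7)
#' fit <- fit_foce(ds, vanco_final_model(), control = foce_control(hessian = FALSE))
#' glance(fit)
fit_foce <- function(data, model, init = NULL, fix = NULL,
                     control = foce_control()) {
  prep <- foce_prep(data)
  pt <- foce_param_table(model)
  if (!is.null(init)) {
    bad <- setdiff(names(init), pt$term)
    if (length(bad)) {
      abort(paste0("Unknown parameter(s) in `init`: ",
                   paste(bad, collapse = ", ")))
    }
    pt$init[match(names(init), pt$term)] <- unname(init)
  }
  if (!is.null(fix)) {
    bad <- setdiff(fix, pt$term)
    if (length(bad)) {
      abort(paste0("Unknown parameter(s) in `fix`: ",
                   paste(bad, collapse = ", ")))
    }
  }
  pt$fixed <- pt$term %in% fix
  # a variance of zero disables its random effect and cannot be estimated
  pt$fixed[pt$kind == "omega" & pt$init == 0] <- TRUE
  if (any(pt$init < 0 & pt$transform == "log")) {
    abort("Log-scale parameters need non-negative initial values.")
  }
  est <- !pt$fixed
  engine <- if (control$engine == "auto") {
    if (model$structural == "one_cmt") "cpp" else "r"
  } else {
    control$engine
  }

  full_from_est <- function(par_est) {
    full <- pt$init
    full[est] <- par_bwd(par_est, pt$transform[est])
    names(full) <- pt$term
    full
  }
  objective <- function(par_est) {
    m <- model_with_params(model, full_from_est(par_est))
    val <- tryCatch(
      foce_eval(prep, m, detail = FALSE, engine = engine,
                inner_tol = control$inner_tol)$ofv,
      error = function(e) NA_real_
    )
    if (!is.finite(val)) 1e10 else val
  }

  start <- par_fwd(pt$init[est], pt$transform[est])
  if (any(est)) {
    opt <- nlminb(start, objective,
                  control = list(iter.max = control$maxit,
                                 eval.max = 4 * control$maxit,
                                 rel.tol = control$rel_tol))
    converged <- opt$convergence == 0
    message <- opt$message
    par_est <- opt$par
  } else {
    converged <- TRUE
    message <- "all parameters fixed"
    par_est <- numeric(0)
  }
  full <- full_from_est(par_est)
  model_fit <- model_with_params(model, full)
  final <- foce_eval(prep, model_fit, detail = TRUE, engine = engine,
                     inner_tol = control$inner_tol)
  boundary <- any(pt$kind == "omega" & est & full[pt$term] < 1e-4)

  se <- rep(NA_real_, nrow(pt))
  if (control$hessian && any(est)) {
    # Hessian of the OFV on the natural scale; Cov = 2 * H^-1 since
    # OFV = -2 log L
    obj_nat <- function(x) {
      fullx <- pt$init
      fullx[est] <- x
      names(fullx) <- pt$term
      m <- model_with_params(model, fullx)
      val <- tryCatch(
        foce_eval(prep, m, detail = FALSE, engine = engine,
                  inner_tol = control$inner_tol)$ofv,
        error = function(e) NA_real_)
      if (!is.finite(val)) 1e10 else val
    }
    H <- tryCatch(pracma::hessian(obj_nat, full[est]),
                  error = function(e) NULL)
    if (!is.null(H)) {
      cov <- tryCatch(2 * solve(H), error = function(e) NULL)
      if (!is.null(cov)) {
        d <- diag(cov)
        d[d < 0] <- NA_real_
        se[est] <- sqrt(d)
      }
    }
    if (all(is.na(se[est]))) {
      warn("Standard errors unavailable: OFV Hessian not invertible.")
    }
  }
  params <- tibble::tibble(
    term = pt$term, estimate = unname(full[pt$term]), fixed = pt$fixed,
    se = se, rse = 100 * se / abs(unname(full[pt$term]))
  )
  res <- tibble::tibble(
    id = prep$obs_id, time = prep$t, tad = prep$tad, dv = prep$y,
    pred = final$pred, ipred = final$ipred, cwres = final$cwres
  )
  structure(list(
    ofv = final$ofv, params = params, model = model, model_fit = model_fit,
    ebes = tibble::tibble(id = prep$ids, eta_cl = final$eta[, 1],
                          eta_v = final$eta[, 2]),
    residuals = res, converged = converged && final$inner_ok,
    boundary = boundary, message = message,
    n_subjects = prep$n_subj, n_obs = length(prep$y),
    data = data, engine = engine, control = control, prep = prep
  ), class = "pk_fit")
}

#' Conditional weighted residuals of a fit
#'
#' Recomputes the per-observation diagnostics from the fitted model:
#' `CWRES = L^-1 (y - yhat)` where `V = L L'` is the FOCE-I observation
#' covariance `G Omega G' + diag(g(eta_hat))` and
#' `yhat = f(eta_hat) - G eta_hat`; `PRED` is the typical-value prediction
#' (`eta = 0`) and `IPRED` the conditional prediction `f(eta_hat)`.
#'
#' @param fit A converged `pk_fit`.
#' @param data Event dataset; defaults to the fitting dataset.
#' @return Tibble with columns `id`, `time`, `tad`, `dv`, `pred`,
#'   `ipred`, `cwres`.
#' @export
compute_cwres <- function(fit, data = fit$data) {
  stopifnot(inherits(fit, "pk_fit"))
  prep <- if (identical(data, fit$data)) fit$prep else foce_prep(data)
  final <- foce_eval(prep, fit$model_fit, detail = TRUE,
                     engine = fit$engine,
                     inner_tol = fit$control$inner_tol)
  tibble::tibble(id = prep$obs_id, time = prep$t, tad = prep$tad,
                 dv = prep$y, pred = final$pred, ipred = final$ipred,
                 cwres = final$cwres)
}

#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf("<pk_fit> OFV %.4f | %d subjects, %d observations | %s\n",
              x$ofv, x$n_subjects, x$n_obs,
              if (x$converged) "converged" else "NOT converged"))
  if (x$boundary) cat("  note: variance estimate near boundary\n")
  print(x$params)
  invisible(x)
}

#' @rdname fit_foce
#' @param x A `pk_fit`.
#' @param ... Unused.
#' @export
tidy.pk_fit <- function(x, ...) x$params

#' @rdname fit_foce
#' @export
glance.pk_fit <- function(x, ...) {
  tibble::tibble(
    ofv = x$ofv, npar = sum(!x$params$fixed), n_subjects = x$n_subjects,
    n_obs = x$n_obs, converged = x$converged, boundary = x$boundary
  )
}

#' @rdname fit_foce
#' @export
augment.pk_fit <- function(x, ...) x$residuals
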