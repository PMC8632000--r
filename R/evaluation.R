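#' Simulate new observations at an existing design
#'
#' Keeps every subject's doses, sampling times and covariates, draws new
#' between-subject random effects and residual errors from `model`, and
#' replaces the observed concentrations. Simulated concentrations are
#' floored at 0 mg/l.
#'
#' @param data Event dataset providing the design.
#' @param model Generating [pk_model()].
#' @param seed Optional integer seed.
#' @return A `pk_dataset` with simulated `dv`.
#' @export
simulate_dataset <- function(data, model, seed = NULL) {
  run <- function() simulate_design_(as_pk_dataset(data), model)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# uses the current RNG stream (callers manage seeding)
simulate_design_ <- function(data, model) {
  prep <- foce_prep(data)
  eta <- sample_etas(model$omega, prep$n_subj)
  ip <- individual_params(prep$covs, model, eta)
  s2 <- sigma_variances(model$error)
  dv <- numeric(length(prep$y))
  for (i in seq_len(prep$n_subj)) {
    osel <- prep$obs_start[i] + seq_len(prep$obs_len[i])
    dsel <- prep$dose_start[i] + seq_len(prep$dose_len[i])
    doses <- tibble::tibble(start_time = prep$d_t0[dsel],
                            amount = prep$d_amt[dsel],
                            duration = prep$d_dur[dsel])
    f <- if (model$structural == "one_cmt") {
      conc_one_cmt(prep$t[osel], ip$cl[i], ip$v[i], doses)
    } else {
      conc_two_cmt(prep$t[osel], ip$cl[i], ip$v[i], model$theta[["q"]],
                   model$theta[["v2"]], doses)
    }
    g <- s2$add + s2$prop * pmax(f, 0.01)^2
    dv[osel] <- pmax(f + rnorm(length(f), 0, sqrt(g)), 0)
  }
  # foce_prep orders observations subject-major with times ascending,
  # which is exactly the row order of the validated dataset
  out <- as_pk_dataset(data)
  obs_rows <- which(out$evid == 0)
  stopifnot(all(out$id[obs_rows] == prep$obs_id),
            all(out$time[obs_rows] == prep$t))
  out$dv[obs_rows] <- dv
  out
}

#' Nonparametric bootstrap of a population PK model
#'
#' Resamples subjects with replacement (all of a subject's rows travel
#' together) to the original subject count, refits the model on each
#' replicate, and summarizes the estimates by their median and 2.5th /
#' 97.5th percentiles. Bias is
#' `100 * (final_estimate - bootstrap_median) / final_estimate`,
#' computed on unrounded medians (positive when the original estimate
#' exceeds the bootstrap median). Replicates that fail to converge are
#' dropped and counted; a warning is attached when more than 20% fail.
#'
#' @param data Event dataset.
#' @param model Model to refit (its values are the reference estimates
#'   and the starting values of every replicate fit).
#' @param n Number of bootstrap replicates.
#' @param seed Optional integer seed.
#' @param control A [foce_control()].
#' @return Object of class `pk_boot`: `summary` (per-parameter tibble),
#'   `estimates` (replicate-level tibble), `n_requested`, `n_converged`,
#'   `warning`.
#' @export
bootstrap_pk <- function(data, model, n = 1000, seed = NULL,
                         control = foce_control(hessian = FALSE)) {
  data <- as_pk_dataset(data)
  ids <- unique(data$id)
  rows_by_id <- split(seq_len(nrow(data)), factor(data$id, levels = ids))
  ref_fit <- fit_foce(data, model, control = control)
  ref <- setNames(ref_fit$params$estimate, ref_fit$params$term)

  one_rep <- function() {
    take <- sample(length(ids), length(ids), replace = TRUE)
    pieces <- lapply(seq_along(take), function(j) {
      block <- data[rows_by_id[[take[j]]], ]
      block$id <- j
      block
    })
    rep_data <- dplyr::bind_rows(pieces)
    class(rep_data) <- class(data)
    f <- tryCatch(
      fit_foce(rep_data, ref_fit$model_fit, control = control),
      error = function(e) NULL
    )
    if (is.null(f) || !f$converged) return(NULL)
    setNames(f$params$estimate, f$params$term)
  }
  run <- function() lapply(seq_len(n), function(i) one_rep())
  reps <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  reps <- reps[!vapply(reps, is.null, logical(1))]
  n_conv <- length(reps)
  warning_msg <- NULL
  if (n_conv < 0.8 * n) {
    warning_msg <- sprintf("only %d of %d bootstrap replicates converged",
                           n_conv, n)
    warn(warning_msg)
  }
  est <- if (n_conv) {
    dplyr::bind_rows(lapply(reps, function(r) {
      tibble::as_tibble(as.list(r))
    }))
  } else {
    tibble::tibble()
  }
  summary <- dplyr::bind_rows(lapply(names(ref), function(term) {
    x <- est[[term]]
    med <- median(x)
    est0 <- unname(ref[term])
    bias <- if (est0 == 0) {
      if (med == 0) 0 else NA_real_
    } else {
      100 * (est0 - med) / est0
    }
    tibble::tibble(
      term = term, estimate = est0, median = med,
      ci_low = unname(quantile(x, 0.025)),
      ci_high = unname(quantile(x, 0.975)),
      bias_percent = bias
    )
  }))
  structure(list(summary = summary, estimates = est, n_requested = n,
                 n_converged = n_conv, warning = warning_msg,
                 ref_fit = ref_fit),
            class = "pk_boot")
}

#' @export
print.pk_boot <- function(x, ...) {
  cat(sprintf("<pk_boot> %d/%d replicates converged\n", x$n_converged,
              x$n_requested))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.pk_boot <- function(x, ...) x$summary

#' @export
glance.pk_boot <- function(x, ...) {
  tibble::tibble(n_requested = x$n_requested, n_converged = x$n_converged,
                 max_abs_bias_percent = max(abs(x$summary$bias_percent)))
}

#' Visual predictive check
#'
#' Simulates `n_sim` replicates of the dataset at the original design
#' (same subjects, doses, times and covariates; new random effects and
#' residual errors), and compares the observed 5th/50th/95th concentration
#' percentiles per time bin with the 90% prediction interval (5th and
#' 95th percentiles across simulations) of each simulated percentile.
#' Bins are quantile-based on time after dose so each bin holds roughly
#' equal numbers of observations. No prediction correction is applied.
#'
#' @param fit A converged `pk_fit` (its `model_fit` is simulated from).
#' @param n_sim Number of simulated datasets.
#' @param bins Number of time bins.
#' @param seed Optional integer seed.
#' @return Object of class `pk_vpc` with `bands` (per bin and percentile:
#'   observed value, simulation median, prediction-interval bounds),
#'   `observed` (binned observations), and `n_sim`.
#' @export
vpc_pk <- function(fit, n_sim = 500, bins = 6, seed = NULL) {
  stopifnot(inherits(fit, "pk_fit"))
  data <- as_pk_dataset(fit$data)
  prep <- fit$prep
  tad <- prep$tad
  probs <- c(0.05, 0.5, 0.95)

  edges <- unique(quantile(tad, probs = seq(0, 1, length.out = bins + 1)))
  if (length(edges) < 3) edges <- range(tad) + c(-1e-9, 1e-9)
  bin <- cut(tad, breaks = edges, include.lowest = TRUE)

  binned_pct <- function(y) {
    out <- matrix(NA_real_, nlevels(bin), 3)
    for (b in seq_len(nlevels(bin))) {
      sel <- bin == levels(bin)[b]
      if (any(sel)) out[b, ] <- quantile(y[sel], probs)
    }
    out
  }
  obs_pct <- binned_pct(prep$y)

  run <- function() {
    sims <- array(NA_real_, c(nlevels(bin), 3, n_sim))
    for (s in seq_len(n_sim)) {
      sim <- simulate_design_(data, fit$model_fit)
      ys <- sim$dv[sim$evid == 0]
      # simulate_design_ preserves row order of the validated dataset,
      # which matches prep's subject-major ordering of observations
      sims[, , s] <- binned_pct(ys)
    }
    sims
  }
  sims <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  mids <- vapply(seq_len(nlevels(bin)), function(b) {
    median(tad[bin == levels(bin)[b]])
  }, numeric(1))
  bands <- dplyr::bind_rows(lapply(seq_len(nlevels(bin)), function(b) {
    dplyr::bind_rows(lapply(seq_along(probs), function(p) {
      x <- sims[b, p, ]
      tibble::tibble(
        bin = levels(bin)[b], bin_mid = mids[b], percentile = 100 * probs[p],
        observed = obs_pct[b, p], sim_median = median(x),
        pi_low = unname(quantile(x, 0.05)),
        pi_high = unname(quantile(x, 0.95))
      )
    }))
  }))
  observed <- tibble::tibble(id = prep$obs_id, tad = tad, dv = prep$y,
                             bin = as.character(bin))
  structure(list(bands = bands, observed = observed, n_sim = n_sim,
                 bins = nlevels(bin)),
            class = "pk_vpc")
}

#' @export
print.pk_vpc <- function(x, ...) {
  cat(sprintf("<pk_vpc> %d simulations, %d time bins\n", x$n_sim, x$bins))
  print(x$bands)
  invisible(x)
}

#' @export
tidy.pk_vpc <- function(x, ...) x$bands

#' Goodness-of-fit table
#'
#' One row per observation with the observed concentration (`dv`), the
#' population prediction (`pred`, eta = 0), the individual prediction
#' (`ipred`, at the empirical Bayes eta), the conditional weighted
#' residual (`cwres`), and the time after dose (`tad`). The CWRES column
#' is the [compute_cwres()] output, the single source of these residuals.
#'
#' @param fit A converged `pk_fit`.
#' @return Tibble with columns `id`, `time`, `tad`, `dv`, `pred`,
#'   `ipred`, `cwres`.
#' @export
gof_tables <- function(fit) {
  stopifnot(inherits(fit, "pk_fit"))
  fit$residuals
}
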