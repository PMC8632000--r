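#' Specify a synthetic study cohort
#'
#' Describes an adult surgical cohort sampled after a single vancomycin
#' infusion: 58 subjects by default, a median age of 54 years (range
#' 25-86), median weight 75 kg (53-129), median serum creatinine
#' 0.935 mg/dl (0.4-4.7), a 39:19 male:female split, doses of 1,000 mg
#' with probability 0.7 (otherwise 500 or 750 mg) infused over 0.5 h, and
#' 1-7 samples per subject (mean about 3) drawn without replacement from
#' a first-dose sampling grid of 0.5-12 h. Continuous covariates follow
#' truncated lognormal distributions centered at the stated medians with
#' hard truncation at the stated ranges.
#'
#' @param n_subjects Number of subjects.
#' @param age,wt,scr Lists with elements `median`, `range` (length-2),
#'   and `sdlog` (log-scale SD before truncation).
#' @param sex_male Proportion of males; the split is deterministic
#'   (`round(n * sex_male)` males).
#' @param dose_levels,dose_probs Dose amounts in mg and their sampling
#'   probabilities.
#' @param t_inf Infusion duration in hours.
#' @param samples_lambda Mean of the Poisson sample-count distribution,
#'   truncated to `[1, length(sample_grid)]`.
#' @param sample_grid Candidate sampling times (hours after infusion
#'   start); times are drawn without replacement.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 58,
                        age = list(median = 54, range = c(25, 86), sdlog = 0.25),
                        wt = list(median = 75, range = c(53, 129), sdlog = 0.18),
                        scr = list(median = 0.935, range = c(0.4, 4.7), sdlog = 0.45),
                        sex_male = 39 / 58,
                        dose_levels = c(500, 750, 1000),
                        dose_probs = c(0.15, 0.15, 0.7),
                        t_inf = 0.5,
                        samples_lambda = 3,
                        sample_grid = c(0.5, 1, 2, 4, 6, 8, 12)) {
  stopifnot(n_subjects >= 1, abs(sum(dose_probs) - 1) < 1e-8,
            length(dose_levels) == length(dose_probs),
            all(sample_grid > 0), sex_male >= 0, sex_male <= 1)
  for (d in list(age, wt, scr)) {
    stopifnot(d$median > 0, length(d$range) == 2, all(d$range > 0),
              d$range[1] < d$median, d$median < d$range[2], d$sdlog > 0)
  }
  structure(list(n_subjects = n_subjects, age = age, wt = wt, scr = scr,
                 sex_male = sex_male, dose_levels = dose_levels,
                 dose_probs = dose_probs, t_inf = t_inf,
                 samples_lambda = samples_lambda, sample_grid = sample_grid),
            class = "cohort_spec")
}

# inverse-CDF draw from a lognormal truncated to [lo, hi], median-centred
rtrunc_lnorm <- function(n, median, sdlog, range) {
  mu <- log(median)
  plo <- plnorm(range[1], mu, sdlog)
  phi <- plnorm(range[2], mu, sdlog)
  qlnorm(runif(n, plo, phi), mu, sdlog)
}

# Poisson truncated to 1..kmax via rejection-free inverse CDF
rtrunc_pois <- function(n, lambda, kmax) {
  k <- seq_len(kmax)
  p <- stats::dpois(k, lambda)
  sample(k, n, replace = TRUE, prob = p)
}

#' Draw a synthetic cohort
#'
#' Samples covariates and a dosing/sampling schedule per subject.
#' Creatinine clearance is always computed from age, weight, sex and
#' serum creatinine via [cockcroft_gault()] (never sampled directly).
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional integer seed.
#' @return Tibble with one row per subject: `id`, `age`, `wt`, `sex`,
#'   `scr`, `crcl`, `dose`, `t_inf`, and the list-column `obs_times`.
#' @export
#' @examples
#' sample_cohort(cohort_spec(n_subjects = 5), seed = 1)
sample_cohort <- function(spec = cohort_spec(), seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  run <- function() {
    n <- spec$n_subjects
    n_male <- round(n * spec$sex_male)
    sex <- c(rep("male", n_male), rep("female", n - n_male))
    age <- rtrunc_lnorm(n, spec$age$median, spec$age$sdlog, spec$age$range)
    wt <- rtrunc_lnorm(n, spec$wt$median, spec$wt$sdlog, spec$wt$range)
    scr <- rtrunc_lnorm(n, spec$scr$median, spec$scr$sdlog, spec$scr$range)
    dose <- sample(spec$dose_levels, n, replace = TRUE,
                   prob = spec$dose_probs)
    n_samp <- rtrunc_pois(n, spec$samples_lambda, length(spec$sample_grid))
    obs_times <- lapply(n_samp, function(k) {
      sort(sample(spec$sample_grid, k, replace = FALSE))
    })
    tibble::tibble(
      id = seq_len(n), age = age, wt = wt, sex = sex, scr = scr,
      crcl = cockcroft_gault(age, wt, scr, sex),
      dose = dose, t_inf = spec$t_inf, obs_times = obs_times
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate concentration data for a cohort
#'
#' Per subject: draws between-subject random effects, computes the
#' individual clearance and volume through the covariate model, evaluates
#' the structural model at the scheduled times, and adds residual error
#' per the model's error specification. Simulated concentrations are
#' floored at 0; values below the assay lower limit of quantification
#' are retained and flagged in the `blq` column.
#'
#' @param cohort Cohort tibble from [sample_cohort()].
#' @param model Generating [pk_model()].
#' @param seed Optional integer seed.
#' @param lloq Assay lower limit of quantification in mg/l.
#' @return A `pk_dataset` with an extra `blq` column; the generating
#'   parameters and per-subject etas are attached as the `"truth"`
#'   attribute.
#' @export
simulate_observations <- function(cohort, model = vanco_final_model(),
                                  seed = NULL, lloq = 0.25) {
  run <- function() {
    n <- nrow(cohort)
    eta <- sample_etas(model$omega, n)
    ip <- individual_params(cohort, model, eta)
    s2 <- sigma_variances(model$error)
    rows <- lapply(seq_len(n), function(i) {
      tt <- cohort$obs_times[[i]]
      doses <- pk_dose(0, cohort$dose[i], cohort$t_inf[i])
      f <- if (model$structural == "one_cmt") {
        conc_one_cmt(tt, ip$cl[i], ip$v[i], doses)
      } else {
        conc_two_cmt(tt, ip$cl[i], ip$v[i], model$theta[["q"]],
                     model$theta[["v2"]], doses)
      }
      g <- s2$add + s2$prop * pmax(f, 0.01)^2
      conc <- pmax(f + rnorm(length(f), 0, sqrt(g)), 0)
      tibble::tibble(
        id = cohort$id[i],
        time = c(0, tt),
        evid = c(1L, rep(0L, length(tt))),
        amt = c(cohort$dose[i], rep(NA_real_, length(tt))),
        rate = c(cohort$dose[i] / cohort$t_inf[i], rep(NA_real_, length(tt))),
        dv = c(NA_real_, conc),
        mdv = c(1L, rep(0L, length(tt))),
        age = cohort$age[i], wt = cohort$wt[i], sex = cohort$sex[i],
        scr = cohort$scr[i], crcl = cohort$crcl[i],
        blq = c(NA, conc < lloq)
      )
    })
    ds <- as_pk_dataset(dplyr::bind_rows(rows))
    attr(ds, "truth") <- list(
      model = model,
      etas = dplyr::bind_cols(tibble::tibble(id = cohort$id), eta)
    )
    ds
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper: draws a cohort via [sample_cohort()] and
#' simulates its concentrations via [simulate_observations()] under a
#' single seed.
#'
#' @param n_subjects Number of subjects.
#' @param model Generating [pk_model()].
#' @param seed Optional integer seed.
#' @param spec Optional [cohort_spec()] (overrides `n_subjects`).
#' @return A `pk_dataset` (see [simulate_observations()]).
#' @export
#' @examples
#' simulate_study(n_subjects = 5, seed = 42)
simulate_study <- function(n_subjects = 58, model = vanco_final_model(),
                           seed = NULL, spec = NULL) {
  if (is.null(spec)) spec <- cohort_spec(n_subjects = n_subjects)
  run <- function() {
    cohort <- sample_cohort(spec)
    simulate_observations(cohort, model)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
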