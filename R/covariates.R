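#' Define a parameter-covariate relation
#'
#' Three functional forms are supported, each contributing a multiplicative
#' factor to the typical value of a PK parameter:
#' \describe{
#'   \item{`linear_centered`}{`1 + value * (cov - center)`; `value` is a
#'     slope per covariate unit, `center` the population median.}
#'   \item{`power_allometric`}{`(cov / center)^value`; `value` is the
#'     fixed exponent, conventionally 0.75 on clearance and 1 on volume.}
#'   \item{`fractional_categorical`}{`1 + value * indicator`; for `sex`
#'     the indicator is 1 for females.}
#' }
#' Factors are floored at 0.01 (with a warning) so that extreme covariate
#' values cannot drive a clearance or volume non-positive: the linear form
#' is unbounded below when extrapolated.
#'
#' @param parameter `"cl"` or `"v"`.
#' @param covariate One of `"age"`, `"sex"`, `"wt"`, `"scr"`, `"crcl"`.
#' @param form Functional form (see Details).
#' @param value Slope (linear/categorical) or exponent (allometric).
#' @param center Centering constant (population median of the covariate);
#'   required for continuous forms.
#' @return One-row tibble; combine relations with [dplyr::bind_rows()].
#' @export
#' @examples
#' cov_relation("cl", "crcl", "linear_centered", 0.0046, center = 101.15)
cov_relation <- function(parameter, covariate,
                         form = c("linear_centered", "power_allometric",
                                  "fractional_categorical"),
                         value, center = NA_real_) {
  parameter <- match.arg(tolower(parameter), c("cl", "v"))
  covariate <- match.arg(tolower(covariate),
                         c("age", "sex", "wt", "scr", "crcl"))
  form <- match.arg(form)
  if (form != "fractional_categorical" && (is.na(center) || center <= 0)) {
    abort("Continuous covariate relations need a positive `center`.")
  }
  if (form == "fractional_categorical" && covariate != "sex") {
    abort("`fractional_categorical` is only defined for `sex`.")
  }
  tibble::tibble(parameter = parameter, covariate = covariate, form = form,
                 value = as.numeric(value), center = as.numeric(center))
}

# multiplicative factor of one relation, vectorized over subjects;
# warn_floor = FALSE is used inside the estimation engine where the
# optimizer may transiently visit extreme slopes
relation_factor <- function(rel, covs, warn_floor = TRUE) {
  cv <- covs[[rel$covariate]]
  if (is.null(cv)) {
    abort(paste0("Covariate `", rel$covariate, "` missing from data."))
  }
  fac <- switch(rel$form,
    linear_centered = 1 + rel$value * (cv - rel$center),
    power_allometric = (cv / rel$center)^rel$value,
    fractional_categorical = 1 + rel$value * (canonical_sex(cv) == "female")
  )
  if (any(fac < 0.01)) {
    if (warn_floor) {
      warn(paste0("Covariate factor for ", rel$parameter, "~",
                  rel$covariate, " floored at 0.01 for ",
                  sum(fac < 0.01), " subject(s)."))
    }
    fac <- pmax(fac, 0.01)
  }
  fac
}

# typical CL and V per subject (no random effects)
typical_params <- function(covs, theta, relations, warn_floor = TRUE) {
  cl <- rep(theta[["cl"]], nrow(covs))
  v <- rep(theta[["v"]], nrow(covs))
  if (!is.null(relations) && nrow(relations)) {
    for (i in seq_len(nrow(relations))) {
      rel <- relations[i, ]
      fac <- relation_factor(rel, covs, warn_floor = warn_floor)
      if (rel$parameter == "cl") cl <- cl * fac else v <- v * fac
    }
  }
  tibble::tibble(cl = cl, v = v)
}

#' Individual PK parameters from covariates and random effects
#'
#' Combines the typical values, the covariate factors, and exponential
#' between-subject random effects:
#' `CL_j = tvcl * prod(factors) * exp(eta_cl)` and likewise for `V_j`.
#' At the covariate medians with `eta = 0` the result equals the typical
#' values exactly.
#'
#' @param covariates Data frame with one row per subject holding the
#'   covariate columns referenced by the model's relations.
#' @param model A [pk_model()].
#' @param eta Optional data frame / matrix with columns `eta_cl`, `eta_v`
#'   (defaults to zero).
#' @return Tibble with columns `cl` (L/h) and `v` (L), one row per subject.
#' @export
#' @examples
#' individual_params(data.frame(crcl = c(20, 101.15, 140), wt = 75),
#'                   vanco_final_model())
individual_params <- function(covariates, model, eta = NULL) {
  covariates <- tibble::as_tibble(covariates)
  tp <- typical_params(covariates, model$theta, model$relations)
  if (is.null(eta)) {
    eta <- tibble::tibble(eta_cl = numeric(nrow(tp)),
                          eta_v = numeric(nrow(tp)))
  }
  eta <- tibble::as_tibble(as.data.frame(eta))
  tibble::tibble(cl = tp$cl * exp(eta$eta_cl), v = tp$v * exp(eta$eta_v))
}

#' Draw between-subject random effects
#'
#' Independent zero-mean normal draws with variances `omega` (log-scale
#' variances of the exponential BSV model).
#'
#' @param omega Named numeric vector `c(cl = ..., v = ...)` of variances
#'   (>= 0); a variance of 0 yields exact zeros.
#' @param n Number of subjects.
#' @param seed Optional integer seed; when supplied the draws are made in
#'   a local RNG scope and are reproducible.
#' @return Tibble with columns `eta_cl`, `eta_v`.
#' @export
sample_etas <- function(omega, n, seed = NULL) {
  stopifnot(n >= 1, all(omega >= 0))
  draw <- function() {
    tibble::tibble(
      eta_cl = if (omega[["cl"]] > 0) rnorm(n, 0, sqrt(omega[["cl"]])) else numeric(n),
      eta_v = if (omega[["v"]] > 0) rnorm(n, 0, sqrt(omega[["v"]])) else numeric(n)
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Convert between BSV variance and percent CV
#'
#' Between-subject variability is reported as a percentage coefficient of
#' variation `100 * sqrt(omega2)`.
#'
#' @param omega2 Variance(s) on the log scale.
#' @return Percent CV.
#' @export
bsv_percent <- function(omega2) 100 * sqrt(omega2)

#' @rdname bsv_percent
#' @param percent Percent CV.
#' @export
omega2_from_bsv <- function(percent) (percent / 100)^2
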