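#' Residual error model
#'
#' @param kind `"additive"`, `"proportional"`, or `"combined"`.
#' @param sigma_add Additive standard deviation in mg/l (additive or
#'   combined).
#' @param sigma_prop Proportional standard deviation (fraction;
#'   proportional or combined).
#' @return An `error_model` list.
#' @export
error_model <- function(kind = c("additive", "proportional", "combined"),
                        sigma_add = NULL, sigma_prop = NULL) {
  kind <- match.arg(kind)
  need_add <- kind %in% c("additive", "combined")
  need_prop <- kind %in% c("proportional", "combined")
  if (need_add && (is.null(sigma_add) || sigma_add <= 0)) {
    abort("`sigma_add` must be > 0 for this error model.")
  }
  if (need_prop && (is.null(sigma_prop) || sigma_prop <= 0)) {
    abort("`sigma_prop` must be > 0 for this error model.")
  }
  if (!need_add) sigma_add <- NULL
  if (!need_prop) sigma_prop <- NULL
  structure(list(kind = kind, sigma_add = sigma_add,
                 sigma_prop = sigma_prop), class = "error_model")
}

#' Declare a population PK model
#'
#' Bundles the structural model, typical parameter values, covariate
#' relations, between-subject variability, and residual error model into
#' one declarative object consumed by [fit_foce()], [vpc_pk()],
#' [simulate_observations()] and [simulate_troughs()].
#'
#' @param structural `"one_cmt"` (default) or `"two_cmt"`.
#' @param theta Named vector of typical values: `cl` (L/h) and `v` (L);
#'   for the two-compartment model also `q` (L/h) and `v2` (L).
#' @param relations Covariate relations, rows from [cov_relation()], or
#'   `NULL` for none.
#' @param omega Named vector `c(cl = ..., v = ...)` of BSV variances on
#'   the log scale (0 disables the random effect).
#' @param error An [error_model()].
#' @return A `pk_model` object.
#' @export
#' @examples
#' pk_model(theta = c(cl = 3, v = 30),
#'          omega = c(cl = 0.09, v = 0.09),
#'          error = error_model("additive", sigma_add = 3))
pk_model <- function(structural = c("one_cmt", "two_cmt"),
                     theta = c(cl = 2.45, v = 22.6),
                     relations = NULL,
                     omega = c(cl = 0, v = 0),
                     error = error_model("additive", sigma_add = 3.07)) {
  structural <- match.arg(structural)
  if (!all(c("cl", "v") %in% names(theta)) || theta[["cl"]] <= 0 ||
      theta[["v"]] <= 0) {
    abort("`theta` needs positive entries `cl` and `v`.")
  }
  if (structural == "two_cmt") {
    if (!all(c("q", "v2") %in% names(theta)) || theta[["q"]] <= 0 ||
        theta[["v2"]] <= 0) {
      abort("Two-compartment model needs positive `q` and `v2` in `theta`.")
    }
  } else if (any(c("q", "v2") %in% names(theta))) {
    abort("`q`/`v2` are only meaningful for the two-compartment model.")
  }
  if (!all(c("cl", "v") %in% names(omega)) || any(omega < 0)) {
    abort("`omega` needs non-negative entries `cl` and `v`.")
  }
  if (!inherits(error, "error_model")) abort("`error` must be an error_model().")
  if (!is.null(relations)) relations <- tibble::as_tibble(relations)
  structure(list(structural = structural, theta = theta,
                 relations = relations, omega = omega[c("cl", "v")],
                 error = error),
            class = "pk_model")
}

#' The reported final vancomycin model
#'
#' One-compartment model with typical clearance 2.45 L/h at the population
#' medians (CRCL 101.15 ml/min, weight 75 kg), typical volume 22.6 L,
#' linear centered covariate effects of CRCL (slope 0.0046 per ml/min) and
#' body weight (slope -0.011 per kg) on clearance, exponential BSV of
#' 11.3% (CL) and 22.8% (V), and additive residual error of 3.07 mg/l.
#'
#' @return A `pk_model`.
#' @export
#' @examples
#' vanco_final_model()
vanco_final_model <- function() {
  pk_model(
    structural = "one_cmt",
    theta = c(cl = 2.45, v = 22.6),
    relations = dplyr::bind_rows(
      cov_relation("cl", "crcl", "linear_centered", 0.0046, center = 101.15),
      cov_relation("cl", "wt", "linear_centered", -0.011, center = 75)
    ),
    omega = c(cl = omega2_from_bsv(11.3), v = omega2_from_bsv(22.8)),
    error = error_model("additive", sigma_add = 3.07)
  )
}

#' A covariate-free base model with neutral starting values
#'
#' @param theta,omega,error As in [pk_model()]; defaults are generic
#'   starting values for a vancomycin-like drug.
#' @return A `pk_model`.
#' @export
vanco_base_model <- function(theta = c(cl = 3, v = 30),
                             omega = c(cl = 0.09, v = 0.09),
                             error = error_model("additive", sigma_add = 3)) {
  pk_model(structural = "one_cmt", theta = theta, relations = NULL,
           omega = omega, error = error)
}

#' @export
print.pk_model <- function(x, ...) {
  cat(sprintf("<pk_model> %s\n", x$structural))
  cat("  theta:", paste(sprintf("%s = %g", names(x$theta), x$theta),
                        collapse = ", "), "\n")
  cat("  BSV %CV:", paste(sprintf("%s = %.3g", names(x$omega),
                                  bsv_percent(x$omega)), collapse = ", "), "\n")
  sig <- c(if (!is.null(x$error$sigma_add))
    sprintf("add = %g mg/l", x$error$sigma_add),
    if (!is.null(x$error$sigma_prop))
      sprintf("prop = %g", x$error$sigma_prop))
  cat(sprintf("  error: %s (%s)\n", x$error$kind, paste(sig, collapse = ", ")))
  if (!is.null(x$relations) && nrow(x$relations)) {
    cat("  relations:\n")
    for (i in seq_len(nrow(x$relations))) {
      r <- x$relations[i, ]
      cat(sprintf("    %s ~ %s [%s] value %g center %g\n", r$parameter,
                  r$covariate, r$form, r$value, r$center))
    }
  }
  invisible(x)
}
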