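#' Monte-Carlo steady-state trough simulation for a renal-function stratum
#'
#' Draws `n` virtual patients at a fixed creatinine clearance, computes
#' each patient's clearance and volume from the covariate model with
#' exponential between-subject variability, and evaluates the closed-form
#' steady-state pre-dose concentration ([ss_trough_one_cmt()]) for the
#' given regimen. Virtual patients share a fixed body weight (default
#' 75 kg, the population median, so the weight factor is 1); residual
#' (assay) error is excluded, so the target range is assessed on the true
#' concentration.
#'
#' @param model A [pk_model()], typically [vanco_final_model()].
#' @param crcl Creatinine clearance level(s) in ml/min; vectorized, one
#'   output row per level.
#' @param dose Dose in mg.
#' @param tau Dosing interval in hours.
#' @param t_inf Infusion duration in hours.
#' @param n Virtual patients per level.
#' @param seed Optional integer seed.
#' @param wt Virtual-patient body weight in kg.
#' @param ttcr Target trough concentration range in mg/l.
#' @return Tibble with one row per CRCL level: `crcl`, `dose`, `tau`,
#'   `t_inf`, `n`, `trough_mean`, `trough_sd`, `fraction_in_ttcr`.
#' @export
#' @examples
#' simulate_troughs(vanco_final_model(), crcl = c(20, 60, 100, 140),
#'                  dose = 1000, n = 200, seed = 1)
simulate_troughs <- function(model, crcl, dose = 1000, tau = 12,
                             t_inf = 0.5, n = 1000, seed = NULL, wt = 75,
                             ttcr = c(10, 20)) {
  stopifnot(n >= 1, all(crcl > 0), wt > 0, length(ttcr) == 2)
  run <- function() {
    purrr::map_dfr(crcl, function(cr) {
      eta <- sample_etas(model$omega, n)
      ip <- individual_params(tibble::tibble(crcl = cr, wt = wt,
                                             age = NA, scr = NA,
                                             sex = "male")[rep(1, n), ],
                              model, eta)
      tr <- ss_trough_one_cmt(dose, tau, t_inf, ip$cl, ip$v)
      tibble::tibble(
        crcl = cr, dose = dose, tau = tau, t_inf = t_inf, n = n,
        trough_mean = mean(tr),
        trough_sd = if (n > 1) sd(tr) else 0,
        fraction_in_ttcr = mean(tr >= ttcr[1] & tr <= ttcr[2])
      )
    })
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Tailor the dose to a target trough range
#'
#' Simulates every candidate dose with common random numbers (one set of
#' virtual patients per CRCL level, shared across doses — the
#' steady-state trough is exactly linear in dose) and selects the dose
#' maximizing the fraction of patients with troughs inside `ttcr`. Ties
#' are broken toward the smaller dose. If no candidate places any patient
#' in range the selection is flagged infeasible.
#'
#' @inheritParams simulate_troughs
#' @param crcl A single creatinine clearance level in ml/min.
#' @param candidate_doses Candidate doses in mg.
#' @return Object of class `pk_tailor`: `selected_dose` (mg), `feasible`,
#'   and `table` (per-candidate trough summaries).
#' @export
#' @examples
#' tailor_dose(vanco_final_model(), crcl = 20, n = 200, seed = 1)
tailor_dose <- function(model, crcl, candidate_doses = seq(200, 1400, by = 100),
                        tau = 12, t_inf = 0.5, n = 1000, seed = NULL,
                        wt = 75, ttcr = c(10, 20)) {
  stopifnot(length(crcl) == 1, length(candidate_doses) >= 1)
  run <- function() {
    eta <- sample_etas(model$omega, n)
    ip <- individual_params(tibble::tibble(crcl = crcl, wt = wt, age = NA,
                                           scr = NA,
                                           sex = "male")[rep(1, n), ],
                            model, eta)
    ref <- ss_trough_one_cmt(1, tau, t_inf, ip$cl, ip$v)  # trough per mg
    purrr::map_dfr(sort(candidate_doses), function(d) {
      tr <- d * ref
      tibble::tibble(
        crcl = crcl, dose = d, tau = tau, t_inf = t_inf, n = n,
        trough_mean = mean(tr),
        trough_sd = if (n > 1) sd(tr) else 0,
        fraction_in_ttcr = mean(tr >= ttcr[1] & tr <= ttcr[2])
      )
    })
  }
  tab <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  feasible <- any(tab$fraction_in_ttcr > 0)
  # sorted ascending, so which.max lands on the smallest tied dose
  selected <- tab$dose[which.max(tab$fraction_in_ttcr)]
  if (!feasible) selected <- NA_real_
  structure(list(selected_dose = selected, feasible = feasible,
                 table = tab, ttcr = ttcr),
            class = "pk_tailor")
}

#' @export
print.pk_tailor <- function(x, ...) {
  if (x$feasible) {
    cat(sprintf("<pk_tailor> selected dose %g mg (target trough %g-%g mg/l)\n",
                x$selected_dose, x$ttcr[1], x$ttcr[2]))
  } else {
    cat("<pk_tailor> infeasible: no candidate placed any trough in range\n")
  }
  print(x$table)
  invisible(x)
}

#' @export
tidy.pk_tailor <- function(x, ...) x$table

#' @export
glance.pk_tailor <- function(x, ...) {
  tibble::tibble(selected_dose = x$selected_dose, feasible = x$feasible,
                 best_fraction = max(x$table$fraction_in_ttcr))
}
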