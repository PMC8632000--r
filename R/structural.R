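#' Build an intravenous infusion dose table
#'
#' @param start_time Infusion start time(s) in hours.
#' @param amount Dose amount(s) in mg (> 0).
#' @param duration Infusion duration(s) in hours (> 0); the infusion rate
#'   is `amount / duration` mg/h.
#' @return Tibble with columns `start_time`, `amount`, `duration`, sorted
#'   by `start_time`.
#' @export
#' @examples
#' pk_dose(0, 1000, 0.5)
#' pk_dose(start_time = seq(0, 36, by = 12), amount = 1000, duration = 0.5)
pk_dose <- function(start_time = 0, amount, duration = 0.5) {
  d <- tibble::tibble(start_time = start_time, amount = amount,
                      duration = duration)
  if (nrow(d) && (any(d$amount <= 0) || any(d$duration <= 0))) {
    abort("`amount` and `duration` must be positive.")
  }
  dplyr::arrange(d, .data$start_time)
}

#' One-compartment concentration after IV infusions
#'
#' Closed-form linear superposition of single-infusion solutions for a
#' one-compartment model with first-order elimination (rate constant
#' `k = cl / v`). During an infusion running at rate `R = amount/duration`
#' the contribution is `(R/cl) * (1 - exp(-k * (t - t0)))`; after the
#' infusion ends, the end-of-infusion concentration decays exponentially.
#'
#' @param t Time(s) in hours since the first dose (vectorized).
#' @param cl Clearance in L/h.
#' @param v Central volume of distribution in L.
#' @param doses Dose table from [pk_dose()] (may be empty).
#' @return Concentrations in mg/l, same length as `t`.
#' @export
#' @examples
#' conc_one_cmt(c(0.5, 2, 12), cl = 2.45, v = 22.6, doses = pk_dose(0, 1000, 0.5))
conc_one_cmt <- function(t, cl, v, doses) {
  stopifnot(cl > 0, v > 0)
  k <- cl / v
  out <- numeric(length(t))
  if (is.null(doses) || nrow(doses) == 0) return(out)
  for (i in seq_len(nrow(doses))) {
    R <- doses$amount[i] / doses$duration[i]
    te <- t - doses$start_time[i]
    dur <- doses$duration[i]
    on <- te > 0 & te <= dur
    off <- te > dur
    out[on] <- out[on] + (R / cl) * (-expm1(-k * te[on]))
    out[off] <- out[off] + (R / cl) * (-expm1(-k * dur)) *
      exp(-k * (te[off] - dur))
  }
  out
}

#' Steady-state trough for q-tau infusion dosing (one compartment)
#'
#' Closed-form pre-dose concentration at steady state for repeated
#' infusions of `dose` mg over `t_inf` h every `tau` h:
#' `C = (dose / (t_inf * cl)) * (1 - exp(-k * t_inf)) /
#'  (1 - exp(-k * tau)) * exp(-k * (tau - t_inf))` with `k = cl / v`.
#' The trough is taken `tau` hours after an infusion start, i.e. the
#' instant before the next dose. All arguments are vectorized.
#'
#' @param dose Dose in mg.
#' @param tau Dosing interval in hours (`tau > t_inf`).
#' @param t_inf Infusion duration in hours.
#' @inheritParams conc_one_cmt
#' @return Trough concentration(s) in mg/l.
#' @export
#' @examples
#' ss_trough_one_cmt(1000, tau = 12, t_inf = 0.5, cl = 1.5354, v = 22.6)
ss_trough_one_cmt <- function(dose, tau, t_inf, cl, v) {
  if (any(t_inf <= 0) || any(tau <= t_inf)) {
    abort("Require tau > t_inf > 0.")
  }
  stopifnot(all(cl > 0), all(v > 0), all(dose >= 0))
  k <- cl / v
  (dose / (t_inf * cl)) * (-expm1(-k * t_inf)) / (-expm1(-k * tau)) *
    exp(-k * (tau - t_inf))
}

#' Two-compartment concentration after IV infusions
#'
#' Standard bi-exponential infusion solution via macro rate constants.
#' With micro constants `k10 = cl/v`, `k12 = q/v`, `k21 = q/v2`, the
#' hybrid constants `alpha`, `beta` solve
#' `alpha + beta = k10 + k12 + k21`, `alpha * beta = k10 * k21`.
#' As `q -> 0` the solution collapses onto the one-compartment curve.
#'
#' @inheritParams conc_one_cmt
#' @param q Inter-compartmental clearance in L/h.
#' @param v2 Peripheral volume in L.
#' @return Central-compartment concentrations in mg/l.
#' @export
conc_two_cmt <- function(t, cl, v, q, v2, doses) {
  if (is.null(q) || is.null(v2) || is.na(q) || is.na(v2)) {
    abort("Two-compartment model requires both `q` and `v2`.")
  }
  stopifnot(cl > 0, v > 0, q > 0, v2 > 0)
  k10 <- cl / v
  k12 <- q / v
  k21 <- q / v2
  s <- k10 + k12 + k21
  root <- sqrt(pmax(s^2 - 4 * k10 * k21, 0))
  alpha <- (s + root) / 2
  beta <- (s - root) / 2
  A1 <- (alpha - k21) / (v * (alpha - beta))
  A2 <- (k21 - beta) / (v * (alpha - beta))
  out <- numeric(length(t))
  if (is.null(doses) || nrow(doses) == 0) return(out)
  # -expm1(-a*t)/a is the stable form of (1 - exp(-a*t))/a for small a
  ramp <- function(a, tt) -expm1(-a * tt) / a
  for (i in seq_len(nrow(doses))) {
    R <- doses$amount[i] / doses$duration[i]
    te <- t - doses$start_time[i]
    dur <- doses$duration[i]
    on <- te > 0 & te <= dur
    off <- te > dur
    out[on] <- out[on] +
      R * (A1 * ramp(alpha, te[on]) + A2 * ramp(beta, te[on]))
    out[off] <- out[off] +
      R * (A1 * ramp(alpha, dur) * exp(-alpha * (te[off] - dur)) +
             A2 * ramp(beta, dur) * exp(-beta * (te[off] - dur)))
  }
  out
}
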