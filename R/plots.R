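#' Goodness-of-fit panels for a fitted model
#'
#' Four standard diagnostic panels: observed vs population predictions,
#' observed vs individual predictions (both with the line of identity),
#' and conditional weighted residuals against population predictions and
#' against time after dose (with guides at 0 and +/-2).
#'
#' @param object A `pk_fit`.
#' @param ... Unused.
#' @return A patchwork object when the patchwork package is installed,
#'   otherwise a list of four ggplots.
#' @export
autoplot.pk_fit <- function(object, ...) {
  g <- gof_tables(object)
  ident <- ggplot2::geom_abline(slope = 1, intercept = 0,
                                linetype = "dashed", colour = "grey40")
  base <- function(p) {
    p + ggplot2::theme_bw()
  }
  p1 <- base(ggplot2::ggplot(g, ggplot2::aes(.data$pred, .data$dv)) +
               ggplot2::geom_point(alpha = 0.6) + ident +
               ggplot2::labs(x = "PRED (mg/l)", y = "DV (mg/l)"))
  p2 <- base(ggplot2::ggplot(g, ggplot2::aes(.data$ipred, .data$dv)) +
               ggplot2::geom_point(alpha = 0.6) + ident +
               ggplot2::labs(x = "IPRED (mg/l)", y = "DV (mg/l)"))
  refs <- list(
    ggplot2::geom_hline(yintercept = 0, colour = "grey40"),
    ggplot2::geom_hline(yintercept = c(-2, 2), linetype = "dashed",
                        colour = "grey60")
  )
  p3 <- base(ggplot2::ggplot(g, ggplot2::aes(.data$pred, .data$cwres)) +
               ggplot2::geom_point(alpha = 0.6) + refs +
               ggplot2::labs(x = "PRED (mg/l)", y = "CWRES"))
  p4 <- base(ggplot2::ggplot(g, ggplot2::aes(.data$tad, .data$cwres)) +
               ggplot2::geom_point(alpha = 0.6) + refs +
               ggplot2::labs(x = "Time after dose (h)", y = "CWRES"))
  if (requireNamespace("patchwork", quietly = TRUE)) {
    (p1 + p2) / (p3 + p4)
  } else {
    list(dv_pred = p1, dv_ipred = p2, cwres_pred = p3, cwres_tad = p4)
  }
}

#' Visual-predictive-check plot
#'
#' Observed percentiles (lines and points) per time bin over the 90%
#' prediction bands of the corresponding simulated percentiles.
#'
#' @param object A `pk_vpc`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pk_vpc <- function(object, ...) {
  b <- object$bands
  b$percentile <- factor(paste0("P", b$percentile),
                         levels = c("P5", "P50", "P95"))
  ggplot2::ggplot(b, ggplot2::aes(.data$bin_mid, group = .data$percentile)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$pi_low,
                                      ymax = .data$pi_high,
                                      fill = .data$percentile),
                         alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed,
                                    colour = .data$percentile)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed,
                                     colour = .data$percentile)) +
    ggplot2::labs(x = "Time after dose (h)", y = "Concentration (mg/l)",
                  colour = "Observed", fill = "Simulated 90% PI") +
    ggplot2::theme_bw()
}

#' Trough-distribution plot for dose tailoring
#'
#' Mean simulated steady-state trough with +/-1 SD bars per candidate
#' dose, against the target trough range.
#'
#' @param object A `pk_tailor`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pk_tailor <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(factor(.data$dose), .data$trough_mean)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = object$ttcr[1], ymax = object$ttcr[2],
                      alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$trough_mean - .data$trough_sd,
      ymax = .data$trough_mean + .data$trough_sd)) +
    ggplot2::labs(x = "Dose (mg)", y = "Steady-state trough (mg/l)") +
    ggplot2::theme_bw()
}
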