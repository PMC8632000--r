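#' Default candidate parameter-covariate relations
#'
#' Builds the candidate set screened by [run_scm()]: linear centered
#' relations for the continuous covariates (centered at the dataset
#' medians) and a fractional effect of sex, on clearance and/or volume.
#' The deterministic screening order is clearance before volume and,
#' within a parameter, CRCL, WT, AGE, SCR, SEX.
#'
#' @param data Event dataset used to compute centering medians.
#' @param parameters Parameters to screen (`"cl"`, `"v"`).
#' @param covariates Covariates to screen.
#' @return Tibble of candidate relations (slope 0, i.e. no effect, as the
#'   starting value).
#' @export
scm_candidates <- function(data, parameters = c("cl", "v"),
                           covariates = c("crcl", "wt", "age", "scr", "sex")) {
  parameters <- match.arg(parameters, c("cl", "v"), several.ok = TRUE)
  covariates <- match.arg(covariates, c("crcl", "wt", "age", "scr", "sex"),
                          several.ok = TRUE)
  data <- as_pk_dataset(data)
  subj <- dplyr::distinct(tibble::as_tibble(data), .data$id, .keep_all = TRUE)
  out <- list()
  for (p in c("cl", "v")) {
    if (!(p %in% parameters)) next
    for (cv in c("crcl", "wt", "age", "scr", "sex")) {
      if (!(cv %in% covariates)) next
      out[[length(out) + 1]] <- if (cv == "sex") {
        cov_relation(p, cv, "fractional_categorical", 0)
      } else {
        cov_relation(p, cv, "linear_centered", 0,
                     center = median(subj[[cv]]))
      }
    }
  }
  dplyr::bind_rows(out)
}

# forward selection rule: best qualifying drop, inclusive threshold,
# ties broken by candidate order (callers order candidates CL-first,
# CRCL/WT/AGE/SCR/SEX within parameter)
scm_pick_forward <- function(drops, threshold) {
  ok <- which(!is.na(drops) & drops >= threshold)
  if (!length(ok)) return(NA_integer_)
  ok[which.max(drops[ok])]
}

# backward elimination rule: weakest relation (smallest OFV rise on
# removal); removed when the rise is below the (inclusive) retention
# threshold
scm_pick_backward <- function(rises, threshold) {
  if (!length(rises) || all(is.na(rises))) return(NA_integer_)
  weakest <- which.min(replace(rises, is.na(rises), Inf))
  if (rises[weakest] < threshold) weakest else NA_integer_
}

#' Stepwise covariate modeling
#'
#' Greedy forward inclusion followed by backward elimination over a set
#' of candidate parameter-covariate relations, using likelihood-ratio
#' criteria on the FOCE-I objective: a candidate is included when adding
#' it drops the OFV by at least `forward_threshold` (3.84, alpha = 0.05,
#' 1 df), taking the largest qualifying drop each round; a retained
#' relation survives backward elimination only if removing it raises the
#' OFV by at least `backward_threshold` (6.63, alpha = 0.01). Both
#' thresholds are inclusive. A candidate whose fit fails to converge is
#' skipped for that round and logged.
#'
#' @param data Event dataset.
#' @param base_model Covariate-free [pk_model()]; must fit successfully.
#' @param candidates Candidate relations, default [scm_candidates()].
#' @param forward_threshold,backward_threshold OFV thresholds.
#' @param control A [foce_control()].
#' @return An object of class `pk_scm`: `steps` (the full decision log),
#'   `final_model`, `final_fit`, and `base_fit`.
#' @export
run_scm <- function(data, base_model, candidates = NULL,
                    forward_threshold = 3.84, backward_threshold = 6.63,
                    control = foce_control(hessian = FALSE)) {
  data <- as_pk_dataset(data)
  if (is.null(candidates)) candidates <- scm_candidates(data)
  candidates <- tibble::as_tibble(candidates)

  current_model <- base_model
  current_fit <- fit_foce(data, current_model, control = control)
  if (!current_fit$converged) {
    abort("Base model did not converge; cannot run SCM.")
  }

  with_relation <- function(model, rel) {
    model$relations <- dplyr::bind_rows(model$relations, rel)
    model
  }
  without_relation <- function(model, i) {
    model$relations <- model$relations[-i, ]
    if (nrow(model$relations) == 0) model$relations <- NULL
    model
  }
  rel_label <- function(rel) paste0(rel$parameter, "~", rel$covariate)

  steps <- list()
  log_step <- function(phase, rel, before, after, decision) {
    steps[[length(steps) + 1]] <<- tibble::tibble(
      phase = phase, parameter = rel$parameter, covariate = rel$covariate,
      ofv_before = before, ofv_after = after,
      delta_ofv = if (phase == "forward") before - after else after - before,
      decision = decision
    )
  }

  remaining <- candidates
  # forward inclusion
  repeat {
    if (nrow(remaining) == 0) break
    drops <- rep(NA_real_, nrow(remaining))
    fits <- vector("list", nrow(remaining))
    for (i in seq_len(nrow(remaining))) {
      f <- tryCatch(
        fit_foce(data, with_relation(current_model, remaining[i, ]),
                 control = control),
        error = function(e) NULL
      )
      if (!is.null(f) && f$converged) {
        fits[[i]] <- f
        drops[i] <- current_fit$ofv - f$ofv
      } else {
        log_step("forward", remaining[i, ], current_fit$ofv, NA_real_,
                 "skipped")
      }
    }
    pick <- scm_pick_forward(drops, forward_threshold)
    for (i in seq_len(nrow(remaining))) {
      if (is.na(drops[i])) next
      if (!is.na(pick) && i == pick) next
      log_step("forward", remaining[i, ], current_fit$ofv, fits[[i]]$ofv,
               "rejected")
    }
    if (is.na(pick)) break
    log_step("forward", remaining[pick, ], current_fit$ofv,
             fits[[pick]]$ofv, "included")
    current_model <- with_relation(current_model, remaining[pick, ])
    current_fit <- fits[[pick]]
    remaining <- remaining[-pick, ]
  }

  # backward elimination
  repeat {
    rel <- current_model$relations
    if (is.null(rel) || nrow(rel) == 0) break
    rises <- rep(NA_real_, nrow(rel))
    fits <- vector("list", nrow(rel))
    for (i in seq_len(nrow(rel))) {
      f <- tryCatch(
        fit_foce(data, without_relation(current_model, i), control = control),
        error = function(e) NULL
      )
      if (!is.null(f) && f$converged) {
        fits[[i]] <- f
        rises[i] <- f$ofv - current_fit$ofv
      } else {
        log_step("backward", rel[i, ], current_fit$ofv, NA_real_, "skipped")
      }
    }
    pick <- scm_pick_backward(rises, backward_threshold)
    if (is.na(pick)) {
      for (i in seq_len(nrow(rel))) {
        if (!is.na(rises[i])) {
          log_step("backward", rel[i, ], current_fit$ofv, fits[[i]]$ofv,
                   "retained")
        }
      }
      break
    }
    log_step("backward", rel[pick, ], current_fit$ofv, fits[[pick]]$ofv,
             "removed")
    current_model <- without_relation(current_model, pick)
    current_fit <- fits[[pick]]
  }

  structure(list(
    steps = if (length(steps)) dplyr::bind_rows(steps) else tibble::tibble(),
    final_model = current_fit$model_fit,
    final_fit = current_fit
  ), class = "pk_scm")
}

#' @export
print.pk_scm <- function(x, ...) {
  rel <- x$final_model$relations
  cat("<pk_scm> final relations:",
      if (is.null(rel) || !nrow(rel)) "none" else
        paste(paste0(rel$parameter, "~", rel$covariate), collapse = ", "),
      "\n")
  cat(sprintf("  final OFV %.4f over %d step decisions\n",
              x$final_fit$ofv, nrow(x$steps)))
  invisible(x)
}

#' @export
tidy.pk_scm <- function(x, ...) x$steps

#' @export
glance.pk_scm <- function(x, ...) {
  rel <- x$final_model$relations
  tibble::tibble(
    n_steps = nrow(x$steps),
    n_relations = if (is.null(rel)) 0L else nrow(rel),
    final_ofv = x$final_fit$ofv,
    converged = x$final_fit$converged
  )
}
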