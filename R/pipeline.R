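#' Default pipeline configuration
#'
#' Nested list mirroring the analysis workflow: a model block (structure,
#' covariate relations, error model), an SCM block (candidates and the
#' 3.84 / 6.63 thresholds), an evaluation block (1,000 bootstrap
#' replicates, 500 VPC simulations, 6 bins), and a dosing block (CRCL
#' levels 20/60/100/140 ml/min, target trough 10-20 mg/l, 1,000 mg q12h
#' over 0.5 h, 1,000 virtual patients). Stages are toggled in
#' `$stages`. Configurations may also be stored as YAML and loaded with
#' [read_run_config()].
#'
#' @return A nested list.
#' @export
default_run_config <- function() {
  list(
    stages = list(fit = TRUE, scm = FALSE, bootstrap = FALSE, vpc = FALSE,
                  dosing = TRUE),
    model = list(
      structural = "one_cmt",
      theta = list(cl = 2.45, v = 22.6),
      relations = list(
        list(parameter = "cl", covariate = "crcl", form = "linear_centered",
             value = 0.0046, center = 101.15),
        list(parameter = "cl", covariate = "wt", form = "linear_centered",
             value = -0.011, center = 75)
      ),
      bsv_percent = list(cl = 11.3, v = 22.8),
      error = list(kind = "additive", sigma_add = 3.07)
    ),
    scm = list(forward_threshold = 3.84, backward_threshold = 6.63,
               parameters = c("cl", "v"),
               covariates = c("crcl", "wt", "age", "scr", "sex")),
    evaluation = list(bootstrap_n = 1000, vpc_n = 500, vpc_bins = 6),
    dosing = list(crcl_levels = c(20, 60, 100, 140), ttcr = c(10, 20),
                  dose = 1000, tau = 12, t_inf = 0.5, n = 1000,
                  candidate_doses = seq(200, 1400, by = 100),
                  tailor = TRUE),
    synthetic = list(n_subjects = 58)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Missing blocks fall back to [default_run_config()]. The file is plain
#' data (no code is evaluated).
#'
#' @param path Path to a YAML file.
#' @return A configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  user <- yaml::read_yaml(path)
  modifyList(default_run_config(), user)
}

# build a pk_model from a config model block
model_from_config <- function(mc) {
  relations <- NULL
  if (length(mc$relations)) {
    relations <- dplyr::bind_rows(lapply(mc$relations, function(r) {
      cov_relation(r$parameter, r$covariate, r$form, r$value,
                   center = if (is.null(r$center)) NA_real_ else r$center)
    }))
  }
  omega <- if (!is.null(mc$bsv_percent)) {
    c(cl = omega2_from_bsv(mc$bsv_percent$cl),
      v = omega2_from_bsv(mc$bsv_percent$v))
  } else if (!is.null(mc$omega)) {
    c(cl = mc$omega$cl, v = mc$omega$v)
  } else {
    c(cl = 0, v = 0)
  }
  err <- error_model(mc$error$kind, sigma_add = mc$error$sigma_add,
                     sigma_prop = mc$error$sigma_prop)
  theta <- unlist(mc$theta)
  pk_model(structural = mc$structural, theta = theta,
           relations = relations, omega = omega, error = err)
}

#' Run the full analysis pipeline
#'
#' Executes fit, SCM, bootstrap, VPC and dosing stages (each optional) in
#' order, writing CSV tables, a consolidated JSON run record containing
#' the seed and the fully resolved configuration, and a plain-text log to
#' `out_dir`. A single global seed deterministically spawns one sub-seed
#' per stage, so re-running with the same configuration, data and seed
#' reproduces every numeric output byte for byte. A stage failure halts
#' downstream stages but preserves artifacts already written.
#'
#' @param config Configuration list ([default_run_config()] /
#'   [read_run_config()]).
#' @param data Event dataset; if `NULL`, either `config$dataset` (a CSV
#'   path) is read or, when absent, a synthetic study of
#'   `config$synthetic$n_subjects` subjects is generated from the model.
#' @param out_dir Output directory (created if needed).
#' @param seed Global integer seed.
#' @return Invisibly, a list with the per-stage results and `out_dir`.
#' @export
run_pipeline <- function(config = default_run_config(), data = NULL,
                         out_dir = tempfile("vancopk_run_"), seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.txt")
  log_line <- function(...) {
    cat(paste0(sprintf(...), "\n"), file = log_path, append = TRUE)
  }
  stage_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, 6))
  names(stage_seeds) <- c("synthetic", "fit", "scm", "bootstrap", "vpc",
                          "dosing")
  model <- model_from_config(config$model)
  results <- list(out_dir = out_dir)

  if (is.null(data)) {
    if (!is.null(config$dataset)) {
      data <- read_pk_dataset(config$dataset)
      log_line("dataset: read %s", config$dataset)
    } else {
      data <- simulate_study(n_subjects = config$synthetic$n_subjects,
                             model = model,
                             seed = stage_seeds[["synthetic"]])
      write_pk_dataset(data, file.path(out_dir, "synthetic_dataset.csv"))
      log_line("dataset: simulated %d subjects (seed %d)",
               config$synthetic$n_subjects, stage_seeds[["synthetic"]])
    }
  }
  data <- as_pk_dataset(data)

  write_num_csv <- function(x, name) {
    readr::write_csv(x, file.path(out_dir, name))
  }
  fail <- function(stage, e) {
    log_line("stage %s FAILED: %s", stage, conditionMessage(e))
    warn(paste0("Pipeline halted at stage `", stage, "`: ",
                conditionMessage(e)))
  }

  fit <- NULL
  halted <- FALSE
  if (isTRUE(config$stages$fit)) {
    fit <- tryCatch({
      f <- fit_foce(data, model)
      write_num_csv(tidy(f), "parameters.csv")
      write_num_csv(f$ebes, "ebes.csv")
      write_num_csv(f$residuals, "residuals.csv")
      jsonlite::write_json(
        list(ofv = f$ofv, converged = f$converged, boundary = f$boundary,
             estimates = setNames(as.list(f$params$estimate),
                                  f$params$term)),
        file.path(out_dir, "fit_summary.json"), auto_unbox = TRUE,
        digits = NA)
      log_line("fit: OFV %.4f, converged %s", f$ofv, f$converged)
      f
    }, error = function(e) {
      fail("fit", e)
      halted <<- TRUE
      NULL
    })
    results$fit <- fit
  }
  model_for_sim <- if (!is.null(fit)) fit$model_fit else model

  if (isTRUE(config$stages$scm) && !halted) {
    results$scm <- tryCatch({
      base <- model
      base$relations <- NULL
      cands <- scm_candidates(data, parameters = config$scm$parameters,
                              covariates = config$scm$covariates)
      s <- run_scm(data, base, candidates = cands,
                   forward_threshold = config$scm$forward_threshold,
                   backward_threshold = config$scm$backward_threshold)
      write_num_csv(tidy(s), "scm_steps.csv")
      log_line("scm: %d final relation(s)", glance(s)$n_relations)
      model_for_sim <- s$final_model
      s
    }, error = function(e) {
      fail("scm", e)
      halted <<- TRUE
      NULL
    })
  }

  if (isTRUE(config$stages$bootstrap) && !halted) {
    results$bootstrap <- tryCatch({
      b <- bootstrap_pk(data, model_for_sim,
                        n = config$evaluation$bootstrap_n,
                        seed = stage_seeds[["bootstrap"]])
      write_num_csv(tidy(b), "bootstrap.csv")
      log_line("bootstrap: %d/%d converged", b$n_converged, b$n_requested)
      b
    }, error = function(e) {
      fail("bootstrap", e)
      halted <<- TRUE
      NULL
    })
  }

  if (isTRUE(config$stages$vpc) && !halted) {
    results$vpc <- tryCatch({
      vfit <- if (!is.null(fit)) fit else fit_foce(data, model_for_sim)
      v <- vpc_pk(vfit, n_sim = config$evaluation$vpc_n,
                  bins = config$evaluation$vpc_bins,
                  seed = stage_seeds[["vpc"]])
      write_num_csv(tidy(v), "vpc_bands.csv")
      log_line("vpc: %d simulations, %d bins", v$n_sim, v$bins)
      v
    }, error = function(e) {
      fail("vpc", e)
      halted <<- TRUE
      NULL
    })
  }

  if (isTRUE(config$stages$dosing) && !halted) {
    results$dosing <- tryCatch({
      dc <- config$dosing
      same <- simulate_troughs(model_for_sim, crcl = dc$crcl_levels,
                               dose = dc$dose, tau = dc$tau,
                               t_inf = dc$t_inf, n = dc$n,
                               seed = stage_seeds[["dosing"]],
                               ttcr = dc$ttcr)
      tailored <- NULL
      if (isTRUE(dc$tailor)) {
        tailored <- purrr::map_dfr(seq_along(dc$crcl_levels), function(i) {
          td <- tailor_dose(model_for_sim, crcl = dc$crcl_levels[i],
                            candidate_doses = dc$candidate_doses,
                            tau = dc$tau, t_inf = dc$t_inf, n = dc$n,
                            seed = stage_seeds[["dosing"]] %% 1000000L + i,
                            ttcr = dc$ttcr)
          dplyr::mutate(
            dplyr::filter(td$table, .data$dose == td$selected_dose),
            selected = TRUE)
        })
      }
      tab <- dplyr::bind_rows(
        dplyr::mutate(same, regimen = "same_dose"),
        if (!is.null(tailored)) dplyr::mutate(tailored,
                                              regimen = "tailored")
      )
      write_num_csv(tab, "dosing.csv")
      log_line("dosing: %d regimen rows", nrow(tab))
      tab
    }, error = function(e) {
      fail("dosing", e)
      NULL
    })
  }

  jsonlite::write_json(
    list(seed = seed, stage_seeds = as.list(stage_seeds),
         config = config,
         package_version = as.character(utils::packageVersion("vancopk")),
         r_version = R.version.string),
    file.path(out_dir, "run_record.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  log_line("run record written")
  invisible(results)
}
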