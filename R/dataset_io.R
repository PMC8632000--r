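#' Default column dialect for event datasets
#'
#' Maps internal (lower-case) field names to the column names expected in
#' CSV files. The defaults follow NONMEM conventions (`ID`, `TIME`, `DV`,
#' `AMT`, `RATE`, `EVID`, `MDV`) plus the covariate columns `AGE`, `WT`,
#' `SEX`, `SCR`, `CRCL`. Supply a modified copy to [read_pk_dataset()] to
#' handle files with other headers.
#'
#' @param ... Named overrides, e.g. `id = "SUBJ"`.
#' @return Named character vector; names are internal field names, values
#'   are file column names.
#' @export
#' @examples
#' pk_dialect()
#' pk_dialect(id = "SUBJ", scr = "CREAT")
pk_dialect <- function(...) {
  d <- c(
    id = "ID", time = "TIME", dv = "DV", amt = "AMT", rate = "RATE",
    evid = "EVID", mdv = "MDV", age = "AGE", wt = "WT", sex = "SEX",
    scr = "SCR", crcl = "CRCL"
  )
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(d))
    if (length(bad)) {
      abort(paste0("Unknown dialect field(s): ", paste(bad, collapse = ", ")))
    }
    d[names(over)] <- over
  }
  d
}

#' Creatinine clearance by the Cockcroft-Gault equation
#'
#' `crcl = (140 - age) * wt / (72 * scr)`, multiplied by 0.85 for females.
#' Units: age in years, weight in kg, serum creatinine in mg/dl; the result
#' is in ml/min. All arguments are vectorized and recycled.
#'
#' @param age Age in years (> 0).
#' @param wt Body weight in kg (> 0).
#' @param scr Serum creatinine in mg/dl (> 0).
#' @param sex Sex; any of `"male"`/`"female"`, `"M"`/`"F"`, or `0`/`1`
#'   (1 = female).
#' @return Numeric vector of creatinine clearance in ml/min.
#' @export
#' @examples
#' cockcroft_gault(54, 75, 0.935, "male")
#' cockcroft_gault(54, 75, 0.935, "female")
cockcroft_gault <- function(age, wt, scr, sex) {
  if (any(scr <= 0)) abort("`scr` must be positive.")
  if (any(age <= 0) || any(wt <= 0)) abort("`age` and `wt` must be positive.")
  sex <- canonical_sex(sex)
  out <- (140 - age) * wt / (72 * scr)
  out * ifelse(sex == "female", 0.85, 1)
}

# accepts 0/1, M/F, male/female (any case); 1 = female
canonical_sex <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1))) abort("Numeric sex codes must be 0 or 1 (1 = female).")
    return(ifelse(x == 1, "female", "male"))
  }
  x <- tolower(as.character(x))
  map <- c(m = "male", male = "male", "0" = "male",
           f = "female", female = "female", "1" = "female")
  bad <- setdiff(unique(x), names(map))
  if (length(bad)) {
    abort(paste0("Unrecognized sex code(s): ", paste(bad, collapse = ", ")))
  }
  unname(map[x])
}

#' Read a NONMEM-style event dataset
#'
#' Reads a rectangular CSV with one row per dose or observation event,
#' validates it, and returns a `pk_dataset` tibble with lower-case column
#' names. Missing values may be empty cells or `"."`. If the `CRCL` column
#' is absent it is computed from `AGE`, `WT`, `SCR`, `SEX` via
#' [cockcroft_gault()]; when present it is taken as authoritative.
#'
#' @param path Path to a CSV file.
#' @param dialect Column-name map from [pk_dialect()].
#' @return A validated `pk_dataset` tibble.
#' @seealso [as_pk_dataset()], [write_pk_dataset()]
#' @export
read_pk_dataset <- function(path, dialect = pk_dialect()) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  # read everything as character: numeric conversion is then done by R's
  # correctly-rounded parser (exact round-trips), and "F" sex codes are
  # never sniffed as logicals
  raw <- tryCatch(
    readr::read_csv(path, na = c("", ".", "NA"), show_col_types = FALSE,
                    col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE),
    error = function(e) abort(paste0("Could not parse ", path, ": ",
                                     conditionMessage(e)))
  )
  if (nrow(raw) == 0 || ncol(raw) == 0) {
    abort(paste0("Schema error: ", path, " contains no data rows."))
  }
  as_pk_dataset(raw, dialect = dialect)
}

#' Coerce and validate an event data frame
#'
#' Validation enforces the event-record invariants: dose rows (`evid == 1`)
#' have `amt > 0` and `rate > 0`; observation rows (`evid == 0`) have
#' `dv >= 0` and `mdv == 0`; times are non-negative and non-decreasing
#' within subject; covariates are constant within subject; and every
#' subject carries at least one dose and one observation. Violations are
#' reported with the offending row numbers.
#'
#' @param x A data frame of event records (file-dialect or internal names).
#' @param dialect Column-name map used to translate file headers; columns
#'   already in internal lower-case form are kept as-is.
#' @param compute_crcl Compute CRCL by Cockcroft-Gault when absent.
#' @return A `pk_dataset` tibble.
#' @export
as_pk_dataset <- function(x, dialect = pk_dialect(), compute_crcl = TRUE) {
  x <- tibble::as_tibble(x)
  # translate file headers to internal names
  for (field in names(dialect)) {
    col <- dialect[[field]]
    if (col %in% names(x) && !(field %in% names(x))) {
      names(x)[names(x) == col] <- field
    }
  }
  required <- c("id", "time", "dv", "amt", "evid", "age", "wt", "sex", "scr")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    abort(paste0("Schema error: missing column(s) ",
                 paste(toupper(missing_cols), collapse = ", "), "."))
  }
  if (!("rate" %in% names(x))) {
    abort("Schema error: missing column RATE (infusion rate, mg/h).")
  }
  # canonical storage types (files arrive as character)
  for (field in c("time", "dv", "amt", "rate", "age", "wt", "scr", "crcl",
                  "id", "evid", "mdv")) {
    if (field %in% names(x) && is.character(x[[field]])) {
      converted <- suppressWarnings(as.numeric(x[[field]]))
      if (any(is.na(converted) & !is.na(x[[field]]))) {
        abort(paste0("Schema error: column ", toupper(field),
                     " contains non-numeric values."))
      }
      x[[field]] <- converted
    }
  }
  if (!("mdv" %in% names(x))) x$mdv <- ifelse(x$evid == 1, 1L, 0L)
  x$sex <- canonical_sex(x$sex)
  if (!("crcl" %in% names(x)) || all(is.na(x$crcl))) {
    if (!compute_crcl) abort("Schema error: missing column CRCL.")
    x$crcl <- cockcroft_gault(x$age, x$wt, x$scr, x$sex)
  }

  problems <- character()
  bad <- function(rows, msg) {
    if (length(rows)) {
      problems <<- c(problems, paste0(msg, " (rows ",
                                      paste(head(rows, 10), collapse = ", "),
                                      if (length(rows) > 10) ", ..." else "",
                                      ")"))
    }
  }
  rows <- seq_len(nrow(x))
  bad(rows[is.na(x$id) | x$id <= 0 | x$id != round(x$id)],
      "subject id must be a positive integer")
  bad(rows[is.na(x$time) | x$time < 0], "time must be >= 0")
  bad(rows[!(x$evid %in% c(0, 1))], "evid must be 0 or 1")
  is_dose <- x$evid == 1
  bad(rows[is_dose & (is.na(x$amt) | x$amt <= 0)],
      "dose rows must have amt > 0")
  bad(rows[is_dose & (is.na(x$rate) | x$rate <= 0)],
      "dose rows must have rate > 0")
  bad(rows[!is_dose & (is.na(x$dv) | x$dv < 0)],
      "observation rows must have dv >= 0")
  bad(rows[!is_dose & x$mdv != 0],
      "observation rows must have mdv = 0")
  for (cv in c("age", "wt", "scr")) {
    bad(rows[is.na(x[[cv]]) | x[[cv]] <= 0],
        paste0(cv, " must be present and positive"))
  }
  ord <- order(x$id, x$time)
  by_id <- split(rows[ord], x$id[ord])
  for (sid in names(by_id)) {
    r <- by_id[[sid]]
    tt <- x$time[r]
    if (is.unsorted(tt)) bad(r[1], paste0("times not sorted for subject ", sid))
    for (cv in c("age", "wt", "sex", "scr", "crcl")) {
      if (length(unique(x[[cv]][r])) > 1) {
        bad(r[1], paste0(cv, " not constant within subject ", sid))
      }
    }
    if (!any(x$evid[r] == 1)) bad(r[1], paste0("subject ", sid, " has no dose"))
    if (!any(x$evid[r] == 0)) {
      bad(r[1], paste0("subject ", sid, " has no observation"))
    }
  }
  if (length(problems)) {
    abort(paste0("Validation error:\n  ",
                 paste(problems, collapse = "\n  ")))
  }

  x$id <- as.integer(x$id)
  x$evid <- as.integer(x$evid)
  x$mdv <- as.integer(x$mdv)
  x <- dplyr::arrange(x, .data$id, .data$time, dplyr::desc(.data$evid))
  core <- c("id", "time", "evid", "amt", "rate", "dv", "mdv",
            "age", "wt", "sex", "scr", "crcl")
  x <- dplyr::relocate(x, dplyr::all_of(core))
  class(x) <- c("pk_dataset", setdiff(class(x), "pk_dataset"))
  x
}

#' Write an event dataset to CSV
#'
#' Writes the standard NONMEM-style header (per `dialect`) with missing
#' values encoded as `"."`. `read_pk_dataset(write_pk_dataset(x, path))`
#' reproduces `x` bit-exactly on all numeric fields.
#'
#' @param data A `pk_dataset` (or coercible data frame).
#' @param path Output file path.
#' @param dialect Column-name map from [pk_dialect()].
#' @return `path`, invisibly.
#' @export
write_pk_dataset <- function(data, path, dialect = pk_dialect()) {
  data <- as_pk_dataset(data)
  out <- as.data.frame(data)[, names(dialect)]
  out$sex <- ifelse(out$sex == "female", 1L, 0L)
  # 17 significant digits guarantee an exact double round-trip
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      v <- sprintf("%.17g", out[[col]])
      v[is.na(out[[col]])] <- NA_character_
      out[[col]] <- v
    }
  }
  names(out) <- unname(dialect)
  tryCatch(
    readr::write_csv(out, path, na = "."),
    error = function(e) abort(paste0("Could not write ", path, ": ",
                                     conditionMessage(e)))
  )
  invisible(path)
}

#' Summarize an event dataset
#'
#' @param data A `pk_dataset`.
#' @return One-row tibble with subject, observation and dose counts and
#'   covariate medians.
#' @export
pk_dataset_summary <- function(data) {
  data <- as_pk_dataset(data)
  subj <- dplyr::distinct(data, .data$id, .keep_all = TRUE)
  tibble::tibble(
    n_subjects = dplyr::n_distinct(data$id),
    n_observations = sum(data$evid == 0),
    n_doses = sum(data$evid == 1),
    median_age = median(subj$age),
    median_wt = median(subj$wt),
    median_scr = median(subj$scr),
    median_crcl = median(subj$crcl),
    n_male = sum(subj$sex == "male"),
    n_female = sum(subj$sex == "female")
  )
}

#' @export
print.pk_dataset <- function(x, ...) {
  s <- pk_dataset_summary(x)
  cat(sprintf("<pk_dataset> %d subjects, %d observations, %d doses\n",
              s$n_subjects, s$n_observations, s$n_doses))
  NextMethod()
}
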