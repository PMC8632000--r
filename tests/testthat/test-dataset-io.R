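test_that("Cockcroft-Gault matches direct arithmetic at the cohort medians", {
  expect_equal(cockcroft_gault(54, 75, 0.935, "male"),
               (140 - 54) * 75 / (72 * 0.935))
  expect_equal(round(cockcroft_gault(54, 75, 0.935, "male"), 2), 95.81)
  expect_equal(cockcroft_gault(54, 75, 0.935, "female"),
               0.85 * cockcroft_gault(54, 75, 0.935, "male"))
  expect_equal(round(cockcroft_gault(54, 75, 0.935, "female"), 2), 81.44)
  expect_equal(cockcroft_gault(140, 75, 1.0, "male"), 0)
})

test_that("Cockcroft-Gault is monotone and validates its domain", {
  ages <- seq(25, 86, by = 1)
  expect_true(all(diff(cockcroft_gault(ages, 75, 1, "male")) < 0))
  wts <- seq(53, 129, by = 2)
  expect_true(all(diff(cockcroft_gault(54, wts, 1, "male")) > 0))
  scrs <- seq(0.4, 4.7, by = 0.1)
  expect_true(all(diff(cockcroft_gault(54, 75, scrs, "male")) < 0))
  expect_error(cockcroft_gault(54, 75, 0, "male"), "positive")
  expect_error(cockcroft_gault(-1, 75, 1, "male"), "positive")
})

test_that("sex codes 0/1, M/F and male/female are equivalent (1 = female)", {
  ref <- cockcroft_gault(54, 75, 1, "female")
  expect_equal(cockcroft_gault(54, 75, 1, 1), ref)
  expect_equal(cockcroft_gault(54, 75, 1, "F"), ref)
  expect_equal(cockcroft_gault(54, 75, 1, "M"),
               cockcroft_gault(54, 75, 1, 0))
  expect_error(cockcroft_gault(54, 75, 1, "x"), "Unrecognized")
})

test_that("write/read round-trip is the identity on a study-sized dataset", {
  ds <- simulate_study(n_subjects = 58, seed = 301)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pk_dataset(ds, path)
  back <- read_pk_dataset(path)
  for (col in c("id", "time", "evid", "amt", "rate", "dv", "mdv",
                "age", "wt", "scr", "crcl")) {
    expect_identical(back[[col]], ds[[col]], label = col)
  }
  expect_identical(back$sex, ds$sex)
  s_in <- pk_dataset_summary(ds)
  s_out <- pk_dataset_summary(back)
  expect_identical(s_out$n_subjects, 58L)
  expect_identical(s_out$n_observations, s_in$n_observations)
})

test_that("minimal one-subject dataset reads with counts (1, 1)", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "ID,TIME,DV,AMT,RATE,EVID,MDV,AGE,WT,SEX,SCR",
    "1,0,.,1000,2000,1,1,54,75,M,0.935",
    "1,2,25.1,.,.,0,0,54,75,M,0.935"
  ), path)
  ds <- read_pk_dataset(path)
  s <- pk_dataset_summary(ds)
  expect_identical(s$n_subjects, 1L)
  expect_identical(s$n_observations, 1L)
  # CRCL column absent: computed via Cockcroft-Gault
  expect_equal(ds$crcl[1], cockcroft_gault(54, 75, 0.935, "male"))
})

test_that("an explicit CRCL column is taken as authoritative", {
  ds <- simulate_study(n_subjects = 3, seed = 5)
  ds$crcl <- 50
  back <- as_pk_dataset(tibble::as_tibble(ds))
  expect_true(all(back$crcl == 50))
})

test_that("schema and validation errors carry row-level diagnostics", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("", path)
  expect_error(read_pk_dataset(path), "[Ss]chema|parse|data")
  writeLines(c("ID,TIME,DV", "1,0,1"), path)
  expect_error(read_pk_dataset(path), "missing column")
  expect_error(read_pk_dataset(tempfile()), "not found")

  good <- simulate_study(n_subjects = 2, seed = 6)
  bad <- tibble::as_tibble(good)
  bad$amt[bad$evid == 1][1] <- -5
  expect_error(as_pk_dataset(bad), "amt > 0")
  bad <- tibble::as_tibble(good)
  bad$time[2] <- -1
  expect_error(as_pk_dataset(bad), "time")
  bad <- tibble::as_tibble(good)
  bad$wt[1] <- 80  # covariate no longer constant within subject
  expect_error(as_pk_dataset(bad), "constant")
  only_obs <- dplyr::filter(tibble::as_tibble(good), evid == 0)
  expect_error(as_pk_dataset(only_obs), "no dose")
})

test_that("writing an empty dataset is an error", {
  expect_error(write_pk_dataset(tibble::tibble(), tempfile()),
               "missing column")
})

test_that("a custom column dialect maps variant headers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "SUBJ,TIME,CONC,AMT,RATE,EVID,MDV,AGE,WT,SEX,CREAT",
    "7,0,.,500,1000,1,1,40,60,F,1.2",
    "7,4,12,.,.,0,0,40,60,F,1.2"
  ), path)
  ds <- read_pk_dataset(path, dialect = pk_dialect(id = "SUBJ", dv = "CONC",
                                                   scr = "CREAT"))
  expect_identical(unique(ds$id), 7L)
  expect_equal(ds$dv[ds$evid == 0], 12)
  expect_error(pk_dialect(nope = "X"), "Unknown dialect")
})
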