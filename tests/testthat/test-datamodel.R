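test_that("dataset construction validates type invariants with subject-attributed messages", {
  ds <- tiny_dataset()
  expect_s3_class(ds, "pk_dataset")
  expect_equal(length(ds$subjects), 2L)
  expect_equal(n_observations(ds), 4L)

  cov <- pk_covariates(wt = 3, pma = 40, ga = 39, pna = 2, scr = 50)
  doses <- data.frame(time = 0, amount = 80, infusion_duration = 0.5)
  obs <- data.frame(time = c(1, 2), conc = c(10, 5), blq = FALSE)

  expect_error(pk_covariates(wt = -1, pma = 40, ga = 39, pna = 2),
               "body weight")
  expect_error(pk_covariates(wt = 3, pma = 38, ga = 39, pna = 2),
               "PMA must be >= GA")
  expect_error(pk_covariates(wt = 3, pma = 40, ga = 39, pna = 2,
                             scr = 0), "SCR")
  expect_error(pk_subject("X", cov, doses[0, ], obs), "at least one dose")
  expect_error(
    pk_subject("X", cov, doses,
               data.frame(time = c(2, 1), conc = c(5, 10), blq = FALSE)),
    "subject X.*non-decreasing")
  expect_error(
    pk_subject("X", cov, doses,
               data.frame(time = c(1, 2), conc = c(-1, 10), blq = FALSE)),
    "positive")
  s <- pk_subject("X", cov, doses, obs)
  expect_error(pk_dataset(list(s, s)), "duplicate subject ids: X")
})

test_that("round-trip write/read through the NONMEM-style CSV is lossless", {
  gen <- sim_dataset(seed = 7, n_subjects = 12)
  ds <- gen$dataset
  path <- withr::local_tempfile(fileext = ".csv")
  write_pk_dataset(ds, path)
  back <- read_pk_dataset(path)
  for (i in seq_along(ds$subjects)) {
    expect_equal(back$subjects[[i]]$subject_id,
                 ds$subjects[[i]]$subject_id)
    expect_equal(back$subjects[[i]]$covariates,
                 ds$subjects[[i]]$covariates)
    expect_equal(back$subjects[[i]]$doses, ds$subjects[[i]]$doses,
                 ignore_attr = TRUE)
    expect_equal(back$subjects[[i]]$observations,
                 ds$subjects[[i]]$observations, ignore_attr = TRUE)
  }
  # and a second pass is byte-identical
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_pk_dataset(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("reader flags BLQ from DV below the LLOQ and reports format errors", {
  df <- data.frame(ID = c(1, 1, 1), TIME = c(0, 1, 8),
                   AMT = c(80, NA, NA), DUR = c(0.5, NA, NA),
                   DV = c(NA, 12, 0.2), EVID = c(1, 0, 0),
                   MDV = c(1, 0, 0), WT = 3.2, PMA = 39.4, GA = 39,
                   PNA = 2, SCR = 56, SEX = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  ds <- read_pk_dataset(path)
  expect_equal(ds$subjects[[1]]$observations$blq, c(FALSE, TRUE))

  utils::write.csv(df[setdiff(names(df), "MDV")], path,
                   row.names = FALSE)
  expect_error(read_pk_dataset(path), "missing mandatory column: MDV")

  df2 <- df
  df2$TIME <- c(0, 8, 1)
  utils::write.csv(df2, path, row.names = FALSE)
  expect_error(read_pk_dataset(path), "subject 1")

  df3 <- df
  df3$WT <- c(3.2, 3.2, 2.9)
  utils::write.csv(df3, path, row.names = FALSE)
  expect_error(read_pk_dataset(path), "WT varies within subject")
})

test_that("SCR mean imputation follows the cohort-mean rule", {
  mk <- function(scrs) {
    subs <- lapply(seq_along(scrs), function(i) {
      pk_subject(paste0("S", i),
                 pk_covariates(wt = 3, pma = 39, ga = 38.5, pna = 2,
                               scr = scrs[i]),
                 data.frame(time = 0, amount = 75,
                            infusion_duration = 0.5),
                 data.frame(time = 1, conc = 10, blq = FALSE))
    })
    pk_dataset(subs)
  }
  # {40, 60, missing} -> 50
  ds <- suppressWarnings(impute_missing_scr(mk(c(40, 60, NA))))
  expect_equal(vapply(ds$subjects, function(s) s$covariates$scr,
                      numeric(1)), c(40, 60, 50))
  expect_warning(impute_missing_scr(mk(c(40, 60, NA))),
                 "exceeds 5%")
  # no missing values: unchanged, non-missing values bit-identical
  ds0 <- mk(c(40.123456789, 60.987654321, 55))
  ds1 <- suppressWarnings(impute_missing_scr(ds0))
  expect_identical(vapply(ds1$subjects, function(s) s$covariates$scr,
                          numeric(1)),
                   vapply(ds0$subjects, function(s) s$covariates$scr,
                          numeric(1)))
  expect_equal(length(ds1$subjects), length(ds0$subjects))
  # all missing is an error
  expect_error(impute_missing_scr(mk(c(NA, NA, NA))), "all SCR")
  # 2 of 72 -> 2.8% and no warning
  scrs <- rep(56.7, 72); scrs[c(10, 20)] <- NA
  expect_no_warning(ds72 <- impute_missing_scr(mk(scrs)))
  rep <- attr(ds72, "scr_imputation")
  expect_equal(rep$n_missing, 2L)
  expect_equal(round(rep$rate_percent, 1), 2.8)
})

test_that("BLQ handling implements discard and loq/2 policies", {
  ds <- tiny_dataset()
  # inject one BLQ record
  ds$subjects[[2]]$observations$conc[2] <- 0.2
  ds$subjects[[2]]$observations$blq[2] <- TRUE
  n0 <- n_observations(ds)

  kept <- handle_blq(ds, "discard")
  expect_equal(n_observations(kept), n0 - 1L)
  expect_equal(attr(kept, "n_blq"), 1L)

  repl <- handle_blq(ds, "loq/2")
  expect_equal(n_observations(repl), n0)
  expect_equal(repl$subjects[[2]]$observations$conc[2], 0.125)
  expect_false(any(repl$subjects[[2]]$observations$blq))

  clean <- handle_blq(tiny_dataset(), "discard")
  expect_equal(n_observations(clean), n0)
  expect_equal(attr(clean, "n_blq"), 0L)

  expect_error(handle_blq(ds, "m3"), "unknown BLQ policy")
})
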