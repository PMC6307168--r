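test_that("a clean dataset is accepted and summarised; invariant violations are rejected", {
  ds <- make_trial(n = 10, seed = 3)
  expect_s3_class(ds, "trial_dataset")
  rep <- validate_trial(ds)
  expect_identical(nrow(rep$errors), 0L)
  expect_true(all(unlist(rep$counts$n_by_arm) > 0))
  expect_true(all(rep$counts$missingness == 0))

  r <- ds$records
  r_bad <- r
  r_bad$utility_w6[1] <- 1.2
  expect_error(trial_dataset(r_bad), "utility in \\(0,1\\]")

  r_bad <- r
  r_bad$womac_w26[2] <- 97
  rep2 <- validate_trial(r_bad)
  expect_identical(nrow(rep2$errors), 1L)
  expect_match(rep2$errors$rule, "WOMAC total in \\[0,96\\]")
  expect_identical(rep2$errors$field, "womac_w26")

  r_bad <- r
  r_bad$id[2] <- r_bad$id[1]
  expect_error(trial_dataset(r_bad), "ids unique")

  r_bad <- r
  r_bad$arm[1] <- "placebo"
  expect_error(trial_dataset(r_bad), "arm one of")
})

test_that("validation counts missingness fractions that match the imposed MAR targets", {
  p <- synthetic_params()
  ds <- impose_missingness(generate_trial(p, seed = 5)$dataset, p, seed = 6)
  rep <- validate_trial(ds)
  # binomial error around the 0.30 utility target at n = 119
  expect_lt(abs(rep$counts$missingness[["utility_w26"]] - 0.30),
            3 * sqrt(0.3 * 0.7 / 119))
  expect_identical(unname(rep$counts$missingness[["utility_w26"]]),
                   unname(ds$meta$realized_missingness[["utility_w26"]]))
  expect_identical(nrow(rep$errors), 0L)
  json <- validation_report_json(rep)
  expect_true(jsonlite::validate(json))
})

test_that("trial tables round-trip through CSV exactly, including missing cells", {
  p <- synthetic_params()
  ds <- impose_missingness(generate_trial(p, seed = 11)$dataset, p, seed = 12)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_table(ds, path)
  ds2 <- read_trial_table(path)
  expect_equal(ds2$records, ds$records, tolerance = 0)
})

test_that("schema mapping and configurable NA tokens are honoured on read", {
  ds <- make_trial(n = 8, seed = 7)
  r <- ds$records
  names(r)[names(r) == "arm"] <- "group"
  names(r)[names(r) == "age"] <- "age_years"
  r$utility_w6[1] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(r, path, na = "-99")
  ds2 <- read_trial_table(path, schema = c(arm = "group", age = "age_years"),
                          na = c("", "NA", "-99"))
  expect_true(is.na(ds2$records$utility_w6[1]))
  expect_identical(ds2$records$arm, ds$records$arm)
  expect_equal(ds2$records$age, ds$records$age)
})

test_that("long-format tables are pivoted to the canonical wide layout on read", {
  ds <- make_trial(n = 6, seed = 9)
  wide <- ds$records
  long <- tidyr::pivot_longer(
    wide,
    cols = tidyr::matches("^(utility|pain|womac|weight)_w(0|6|26)$"),
    names_to = c(".value", "week"),
    names_pattern = "(.*)_w(\\d+)"
  )
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(long, path, na = "")
  ds2 <- read_trial_table(path, format = "long")
  expect_equal(ds2$records[trial_columns()], wide[trial_columns()])
})

test_that("population selection: ITT is the identity, per-protocol thresholds the active arm only", {
  ds <- make_trial(n = 12, seed = 21)
  itt <- select_population(ds, "itt")
  expect_equal(itt$records, ds$records)
  expect_equal(select_population(itt, "itt")$records, itt$records)

  r <- ds$records
  is_int <- r$arm == "intervention"
  r$ghs_calls[is_int] <- rep(c(0, 6, 10), length.out = sum(is_int))
  ds2 <- trial_dataset(r)
  pp <- select_population(ds2, "per_protocol", min_calls = 6)
  expect_identical(sum(pp$records$arm == "intervention"),
                   sum(r$ghs_calls[is_int] >= 6))
  expect_identical(sum(pp$records$arm == "control"), sum(!is_int))
  expect_error(select_population(ds2, "per_protocol", min_calls = -1),
               ">= 0")
})

test_that("per-protocol selection matches a direct enumeration of the call distribution", {
  for (s in 1:4) {
    ds <- make_trial(n = 119, seed = 100 + s)
    r <- ds$records
    is_int <- r$arm == "intervention"
    pp <- select_population(ds, "per_protocol", min_calls = 6)
    expect_identical(sum(pp$records$arm == "intervention"),
                     sum(r$ghs_calls[is_int] >= 6))
    expect_identical(sum(pp$records$arm == "control"), sum(!is_int))
    expect_lte(nrow(pp$records), nrow(r))
    # order of the retained rows is preserved
    expect_identical(pp$records$id,
                     r$id[!is_int | r$ghs_calls >= 6])
  }
})
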