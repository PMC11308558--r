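test_that("the shipped laboratory dictionary loads with 53 variable specs", {
  f <- system.file("extdata", "bacteremia_dictionary.csv", package = "idascreen")
  dict <- read_data_dictionary(f)
  expect_equal(nrow(dict), 53L)
  expect_equal(sum(dict$role == "outcome"), 1L)
  expect_equal(sum(dict$role == "identifier"), 1L)
  expect_equal(length(setdiff(dict$name, c("ID", dict$name[dict$role == "outcome"]))), 51L)
  # part-whole and ratio relations are machine-readable
  expect_setequal(dict$name[!is.na(dict$component_of)], c("NEU", "BASO", "EOS", "LYM", "MONO"))
  expect_equal(dict$ratio_of[dict$name == "NEUR"], "NEU")
})

test_that("dictionary reading rejects duplicates and unknown tokens", {
  dup <- write_fixture(c(
    "name,scale,role",
    "Y,binary,outcome", "AGE,continuous,structural", "AGE,continuous,key"
  ))
  expect_error(read_data_dictionary(dup), "Duplicate.*AGE")

  badrole <- write_fixture(c(
    "name,scale,role",
    "Y,binary,outcome", "AGE,continuous,structural", "X,continuous,covariate"
  ))
  expect_error(read_data_dictionary(badrole), "covariate")

  badscale <- write_fixture(c(
    "name,scale,role",
    "Y,binary,outcome", "AGE,continuous,structural", "X,numeric,key"
  ))
  expect_error(read_data_dictionary(badscale), "numeric")
})

test_that("dictionary invariants: outcome, structural, relations, limits", {
  no_outcome <- write_fixture(c("name,scale,role", "AGE,continuous,structural"))
  expect_error(read_data_dictionary(no_outcome), "outcome")
  bad_ref <- write_fixture(c(
    "name,scale,role,component_of",
    "Y,binary,outcome,", "AGE,continuous,structural,", "NEU,continuous,key,WBC"
  ))
  expect_error(read_data_dictionary(bad_ref), "WBC")
  bad_lim <- write_fixture(c(
    "name,scale,role,lower,upper",
    "Y,binary,outcome,,", "AGE,continuous,structural,120,10"
  ))
  expect_error(read_data_dictionary(bad_lim), "lower > upper")
})

test_that("dictionary write/read round-trips field by field", {
  dict <- default_study()$dictionary
  f <- withr::local_tempfile(fileext = ".csv")
  write_data_dictionary(dict, f)
  back <- read_data_dictionary(f)
  expect_equal(as.data.frame(back), as.data.frame(dict))
})

test_that("dataset reading counts missing cells and limit violations without altering values", {
  dict <- toy_dict()
  f <- write_fixture(c(
    "ID,Y,AGE,SEX,A,B",
    "1,no,50,1,0.5,",
    "2,yes,-3,2,1.25,2.0",
    "3,no,70,1,NA,0.125",
    "4,no,61,2,0.75,"
  ))
  ds <- read_dataset(f, dict)
  expect_equal(sum(is.na(ds$B)), 2L)
  expect_equal(sum(is.na(ds$A)), 1L)
  # AGE = -3 is below the declared lower limit: loaded, counted
  expect_equal(ds$AGE[2], -3)
  lv <- attr(ds, "limit_violations")
  expect_equal(lv$n_violations[lv$variable == "AGE"], 1L)
  # locale-independent '.' decimal parsing, values untouched
  expect_identical(ds$A, c(0.5, 1.25, NA, 0.75))
})

test_that("dataset reading rejects columns missing from the dictionary", {
  f <- write_fixture(c("ID,Y,AGE,SEX,XYZ", "1,no,50,1,3"))
  expect_error(read_dataset(f, toy_dict()), "XYZ")
})

test_that("plan validation reports issues without throwing, and is pure", {
  dict <- toy_dict()
  ds <- as_toy_dataset(toy_data())
  good <- toy_plan()
  v <- validate_plan(good, dict, ds)
  expect_equal(sum(v$severity == "error"), 0L)

  typo <- ida_plan(model_sets = list(key = c("AGE", "HB")))
  v2 <- validate_plan(typo, dict, ds)
  expect_true(any(v2$severity == "error" & v2$variable == "HB"))

  degenerate <- ida_plan(
    model_sets = list(key = c("A", "B")),
    interactions = list(c("AGE", "AGE"))
  )
  v3 <- validate_plan(degenerate, dict, ds)
  expect_true(any(v3$code == "DEGENERATE_INTERACTION"))

  # purity: identical inputs give identical reports
  expect_identical(
    validate_plan(degenerate, dict, ds),
    validate_plan(degenerate, dict, ds)
  )
})

test_that("structural variables with missing values raise a warning entry", {
  dict <- toy_dict()
  dat <- toy_data()
  dat$AGE[3] <- NA
  v <- validate_plan(toy_plan(), dict, as_toy_dataset(dat))
  expect_true(any(v$code == "STRUCTURAL_MISSING" & v$variable == "AGE"))
  expect_false(any(v$severity == "error"))
})
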