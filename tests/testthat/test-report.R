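test_that("the report covers every checklist item with a tagged section", {
  bundle <- default_bundle()
  md <- render_report(bundle, "markdown")
  items <- c(
    "PRE1", "PRE2", "PRE3", "PRE4", "M1", "M2", "M3", "M4", "ME1",
    "U1", "U2", "UE1", "V1", "V2", "V3", "VE1", "VE2", "VE3"
  )
  for (it in items) {
    expect_match(md, sprintf("\\[%s\\]", it), info = it)
  }
  expect_identical(bundle$checklist$item, items)
  # unit missingness is explicitly not evaluable in a registry export
  expect_match(md, "not evaluable")
})

test_that("JSON rendering is loss-free for the screening numbers", {
  bundle <- default_bundle()
  parsed <- jsonlite::fromJSON(render_report(bundle, "json"), simplifyVector = TRUE)
  expect_equal(parsed$missingness$item$proportion, bundle$missingness$item$proportion)
  expect_equal(
    parsed$missingness$cascade$n_complete,
    bundle$missingness$cascade$n_complete
  )
  expect_equal(
    parsed$multivariate$vif$key$linear$table$vif,
    bundle$multivariate$vif$key$linear$table$vif
  )
  expect_equal(parsed$transforms$r_raw, bundle$transforms$r_raw)
  cont <- parsed$univariate$continuous
  expect_equal(
    cont$mode_proportion[cont$variable == "BASO"],
    bundle$univariate$continuous$mode_proportion[bundle$univariate$continuous$variable == "BASO"]
  )
  expect_equal(parsed$provenance$seed, bundle$provenance$seed)
})

test_that("unknown report formats error; html wraps the markdown", {
  bundle <- default_bundle()
  expect_error(render_report(bundle, "pdf"), "format")
  html <- render_report(bundle, "html")
  expect_match(html, "^<!DOCTYPE html>")
  expect_match(html, "\\[M2\\]")
})

test_that("run_ida produces a complete report directory from files, deterministically", {
  dir <- withr::local_tempdir()
  st <- default_study(n_rows = 250)
  write_synthetic_study(st, file.path(dir, "in"))
  out1 <- file.path(dir, "out1")
  status <- run_ida(
    data = file.path(dir, "in", "data.csv"),
    dictionary = file.path(dir, "in", "dictionary.csv"),
    plan = file.path(dir, "in", "plan.yaml"),
    out = out1, quiet = TRUE
  )
  expect_equal(status, 0L)
  expect_true(all(file.exists(file.path(out1, c(
    "report.md", "results.json", "validation.csv",
    "item_missingness.csv", "complete_case_cascade.csv",
    "transform_decisions.csv", "correlations_long.csv",
    "missingness_dendrogram.nwk"
  )))))

  out2 <- file.path(dir, "out2")
  run_ida(
    data = file.path(dir, "in", "data.csv"),
    dictionary = file.path(dir, "in", "dictionary.csv"),
    plan = file.path(dir, "in", "plan.yaml"),
    out = out2, quiet = TRUE
  )
  expect_identical(
    readLines(file.path(out1, "results.json")),
    readLines(file.path(out2, "results.json"))
  )
})

test_that("run_ida fails cleanly on a plan referencing unknown variables", {
  dir <- withr::local_tempdir()
  st <- default_study(n_rows = 250)
  write_synthetic_study(st, file.path(dir, "in"))
  plan <- st$plan
  plan$model_sets$key <- c(plan$model_sets$key, "HB")
  write_ida_plan(plan, file.path(dir, "in", "bad_plan.yaml"))
  status <- run_ida(
    data = file.path(dir, "in", "data.csv"),
    dictionary = file.path(dir, "in", "dictionary.csv"),
    plan = file.path(dir, "in", "bad_plan.yaml"),
    out = file.path(dir, "out"), quiet = TRUE
  )
  expect_equal(status, 1L)
  v <- readr::read_csv(file.path(dir, "out", "validation.csv"), show_col_types = FALSE)
  expect_true(any(v$severity == "error" & v$variable == "HB"))
})

test_that("the shipped plan validates against the shipped dictionary", {
  dict <- read_data_dictionary(
    system.file("extdata", "bacteremia_dictionary.csv", package = "idascreen")
  )
  plan <- read_ida_plan(
    system.file("extdata", "bacteremia_plan.yaml", package = "idascreen")
  )
  expect_setequal(plan$model_sets$all, dict$name[!dict$role %in% c("identifier", "outcome")])
  expect_equal(length(plan$model_sets), 4L)
})
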