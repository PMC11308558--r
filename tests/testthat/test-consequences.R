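# A minimal hand-built bundle exercising each rule in isolation.
mini_bundle <- function(item = NULL, discordance = NULL, spikes = list(),
                        spearman = NULL, categorical = list()) {
  list(
    missingness = list(item = item, discordance = discordance),
    univariate = list(spikes = spikes, categorical = categorical),
    multivariate = list(spearman = spearman)
  )
}

mini_cormat <- function(vars, r) {
  dimnames(r) <- list(vars, vars)
  structure(
    list(
      variables = vars, method = "spearman", r = r,
      n_pairs = matrix(100, nrow(r), ncol(r)), unreliable = r < -2
    ),
    class = "ida_cormat"
  )
}

test_that("missingness rules fire in disjoint bands, omission superseding review", {
  dict <- toy_dict()
  plan <- ida_plan()
  item <- tibble::tibble(
    variable = c("A", "B", "C", "AGE"),
    role = c("key", "key", "minor", "structural"),
    n_total = 100L,
    n_missing = c(40L, 25L, 10L, 0L),
    proportion = c(0.40, 0.25, 0.10, 0)
  )
  f <- apply_consequence_rules(mini_bundle(item = item), dict, plan)
  expect_equal(f$rule_id[vapply(f$variables, identical, TRUE, "A")], "HIGH_MISSING_OMIT")
  expect_equal(f$rule_id[vapply(f$variables, identical, TRUE, "B")], "HIGH_MISSING_REVIEW")
  expect_false(any(vapply(f$variables, identical, TRUE, "C")))
  # evidence values are the bundle's values, verbatim
  expect_equal(f$evidence[[1]]$missing_proportion, 0.40)
})

test_that("correlated-missingness blocks need low discordance AND high missingness", {
  dict <- toy_dict()
  plan <- ida_plan()
  item <- tibble::tibble(
    variable = c("A", "B", "C"), role = "minor", n_total = 100L,
    n_missing = c(30L, 30L, 30L), proportion = c(0.3, 0.3, 0.3)
  )
  d <- matrix(c(0, 0.02, 0.4, 0.02, 0, 0.4, 0.4, 0.4, 0), 3, 3,
    dimnames = list(c("A", "B", "C"), c("A", "B", "C"))
  )
  class(d) <- c("ida_discordance", "matrix", "array")
  attr(d, "missing_proportion") <- c(A = 0.3, B = 0.3, C = 0.3)
  f <- apply_consequence_rules(mini_bundle(item = item, discordance = d), dict, plan)
  blocks <- f[f$rule_id == "CORRELATED_MISSINGNESS_BLOCK", ]
  expect_equal(nrow(blocks), 1L)
  expect_setequal(blocks$variables[[1]], c("A", "B"))
})

test_that("part-whole and ratio links take precedence over a plain collinear pair", {
  dict <- toy_dict(extra = tibble::tibble(
    name = c("WBC", "NEU", "NEUR"),
    label = NA, scale = "continuous", units = NA, role = "minor",
    lower = NA_real_, upper = NA_real_,
    component_of = c(NA, "WBC", NA), ratio_of = c(NA, NA, "NEU")
  ))
  plan <- ida_plan()
  r <- diag(4)
  vars <- c("WBC", "NEU", "NEUR", "C")
  r[1, 2] <- r[2, 1] <- 0.93
  r[2, 3] <- r[3, 2] <- 0.9
  r[1, 4] <- r[4, 1] <- 0.85
  f <- apply_consequence_rules(mini_bundle(spearman = mini_cormat(vars, r)), dict, plan)
  pw <- f[f$rule_id == "PART_WHOLE_REPARAM", ]
  expect_equal(nrow(pw), 1L)
  expect_setequal(pw$variables[[1]], c("WBC", "NEU"))
  expect_equal(pw$evidence[[1]]$derived_variable$new_name, "WBC_NONEU")
  expect_equal(pw$evidence[[1]]$derived_variable$formula, "WBC - NEU")
  expect_equal(pw$severity, "reparameterize")
  expect_equal(sum(f$rule_id == "RATIO_REDUNDANT"), 1L)
  expect_equal(sum(f$rule_id == "COLLINEAR_PAIR"), 1L) # WBC-C has no declared link
})

test_that("sparse categorical levels suggest collapsing; spikes become discard candidates", {
  dict <- toy_dict()
  plan <- ida_plan()
  cs <- list(SEX = list(
    variable = "SEX", n_nonmissing = 100L, n_missing = 0L,
    levels = tibble::tibble(level = c("1", "2"), count = c(95L, 5L), proportion = c(0.95, 0.05)),
    collapsed = NULL
  ))
  spikes <- list(A = structure(
    list(
      variable = "A", mode_value = 0, mode_proportion = 0.87,
      concentration_ratio = 15.7,
      top_values = tibble::tibble(value = 0, count = 87L)
    ),
    class = "ida_spike_flag"
  ))
  f <- apply_consequence_rules(mini_bundle(spikes = spikes, categorical = cs), dict, plan)
  expect_setequal(f$rule_id, c("SPIKE_DEGENERATE", "SPARSE_CATEGORY_COLLAPSE"))
  expect_equal(f$severity[f$rule_id == "SPIKE_DEGENERATE"], "discard_candidate")
})

test_that("clean independent data triggers no findings", {
  n <- 400
  withr::with_seed(26, {
    dat <- toy_data(n)
    dat$A <- rnorm(n)
    dat$B <- rnorm(n)
    dat$C <- rnorm(n, 10, 1)
  })
  st_dict <- toy_dict()
  bundle <- ida_screen(as_toy_dataset(dat), st_dict, toy_plan())
  expect_equal(nrow(bundle$findings), 0L)
  expect_match(bundle$amendments$statement, "No amendments")
})

test_that("findings are deterministic and blind to the outcome", {
  st <- default_study(n_rows = 400)
  b_blind <- ida_screen(st$data, st$dictionary, st$plan, blind = TRUE)
  b_open <- ida_screen(st$data, st$dictionary, st$plan, blind = FALSE)
  expect_equal(
    as.data.frame(b_blind$findings),
    as.data.frame(b_open$findings)
  )
  b_blind2 <- ida_screen(st$data, st$dictionary, st$plan, blind = TRUE)
  expect_identical(as.data.frame(b_blind$findings), as.data.frame(b_blind2$findings))
})

test_that("the amendment summary merges multi-rule variables and counts the delta", {
  bundle <- default_bundle()
  am <- bundle$amendments
  expect_equal(am$n_predictors, 51L)
  expect_equal(am$n_remaining, am$n_predictors - am$n_discard_candidates)
  # PAMY exceeds both the omission threshold and sits in a missingness block
  pam <- am$merged_by_variable[am$merged_by_variable$variable == "PAMY", ]
  expect_match(pam$rules, "CORRELATED_MISSINGNESS_BLOCK")
  expect_match(pam$rules, "HIGH_MISSING_OMIT")

  empty <- amendment_summary(
    bundle$findings[0, ], bundle$provenance$plan, default_study()$dictionary
  )
  expect_match(empty$statement, "No amendments")
})

test_that("derived-variable definitions validate their sources", {
  dict <- default_study()$dictionary
  d <- derived_variable_def("WBC", "NEU", dict)
  expect_equal(d$new_name, "WBC_NONEU")
  expect_error(derived_variable_def("WBC", "NOPE", dict), "must exist")
})
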