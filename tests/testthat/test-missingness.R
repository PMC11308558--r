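test_that("unit missingness passes counts through or reports not evaluable", {
  expect_s3_class(unit_missingness_summary(), "ida_not_evaluable")
  tab <- unit_missingness_summary(eligible = 100, assessed = 80, recruited = 70)
  expect_equal(tab$attrition, c(NA, 0.2, 0.125))
  expect_error(unit_missingness_summary(assessed = 70, recruited = 80), "non-increasing")
  expect_error(unit_missingness_summary(eligible = -1), "non-negative")
})

test_that("item missingness counts and proportions are exact", {
  dat <- toy_data(n = 10)
  dat$B[c(1, 4, 7)] <- NA
  im <- item_missingness(as_toy_dataset(dat), toy_dict())
  expect_equal(im$proportion[im$variable == "B"], 0.3)
  expect_equal(im$n_missing[im$variable == "AGE"], 0L)
  # identifier excluded, outcome included
  expect_false("ID" %in% im$variable)
  expect_true("Y" %in% im$variable)
})

test_that("complete-case cascade matches hand enumeration and handles edge cases", {
  dat <- toy_data(n = 5)
  dat$A[c(1, 2)] <- NA
  dat$B[c(2, 3)] <- NA
  ds <- as_toy_dataset(dat)
  plan <- ida_plan(model_sets = list(ab = c("A", "B")))
  cc <- complete_case_cascade(ds, plan, toy_dict())
  expect_equal(cc$n_complete[cc$set_name == "ab"], 2L)
  expect_equal(cc$proportion_complete[cc$set_name == "ab"], 2 / 5)

  full <- complete_case_cascade(as_toy_dataset(toy_data(5)), plan, toy_dict())
  expect_true(all(full$proportion_complete == 1))

  expect_error(
    complete_case_cascade(ds, ida_plan(model_sets = list(empty = character(0))), toy_dict()),
    "empty"
  )
})

test_that("cascade equals brute-force row enumeration and is monotone in the set", {
  st <- default_study(n_rows = 200)
  dict <- st$dictionary
  preds <- setdiff(dict$name[dict$role %in% c("key", "medium", "minor")], character(0))
  withr::with_seed(31, {
    for (rep in 1:5) {
      members <- sample(preds, sample(3:10, 1))
      nested <- list(s1 = members[1:2], s2 = members[1:4], s3 = members)
      plan <- ida_plan(model_sets = nested)
      cc <- complete_case_cascade(st$data, plan, dict)
      # brute force: loop rows, check each cell
      brute <- vapply(nested, function(m) {
        sum(vapply(seq_len(nrow(st$data)), function(i) {
          !anyNA(unlist(st$data[i, c("BloodCulture", m)]))
        }, logical(1)))
      }, numeric(1))
      expect_equal(cc$n_complete[match(names(nested), cc$set_name)], unname(brute))
      expect_true(all(diff(cc$n_complete[-1]) <= 0))
    }
  })
})

test_that("stratified cascade brackets the overall proportion", {
  st <- default_study(n_rows = 400)
  plan <- st$plan
  overall <- complete_case_cascade(st$data, plan, st$dictionary)
  strat <- stratified_complete_cases(st$data, plan, st$dictionary)
  for (s in unique(strat$set_name)) {
    props <- strat$proportion_complete[strat$set_name == s]
    ov <- overall$proportion_complete[overall$set_name == s]
    expect_lte(min(props), ov + 1e-12)
    expect_gte(max(props), ov - 1e-12)
  }
  expect_true(all(strat$small_stratum[strat$n_rows < 10]))
})

test_that("discordance matrix is exact and obeys its bounds", {
  dat <- toy_data(n = 10)
  dat$A[c(1, 2)] <- NA
  dat$B[3] <- NA
  ds <- as_toy_dataset(dat)
  d <- missingness_discordance_matrix(ds, c("A", "B", "C"))
  expect_equal(d["A", "B"], 0.3)
  expect_equal(d["A", "C"], 0.2) # C complete: discordance equals A's proportion
  expect_equal(unname(diag(d)), rep(0, 3))

  # bounds |p_i - p_j| <= d <= min(1, p_i + p_j) on random patterns,
  # checked against brute-force indicator comparison
  withr::with_seed(7, {
    n <- 150
    dat2 <- toy_data(n)
    for (v in c("A", "B", "C")) dat2[[v]][runif(n) < 0.3] <- NA
    ds2 <- as_toy_dataset(dat2)
    d2 <- missingness_discordance_matrix(ds2, c("A", "B", "C"))
    p <- attr(d2, "missing_proportion")
    for (i in 1:2) {
      for (j in (i + 1):3) {
        brute <- mean(is.na(dat2[[c("A", "B", "C")[i]]]) != is.na(dat2[[c("A", "B", "C")[j]]]))
        expect_equal(d2[i, j], brute)
        expect_gte(d2[i, j], abs(p[i] - p[j]) - 1e-12)
        expect_lte(d2[i, j], min(1, p[i] + p[j]) + 1e-12)
      }
    }
  })
})

test_that("missingness clustering merges identical patterns first", {
  # A and B share a pattern exactly, C is discordant with both at 0.4
  dat <- toy_data(n = 10)
  dat$A[1:2] <- NA
  dat$B[1:2] <- NA
  dat$C[3:6] <- NA
  ds <- as_toy_dataset(dat)
  d <- missingness_discordance_matrix(ds, c("A", "B", "C"))
  dend <- cluster_missingness(d)
  merges <- dendrogram_merges(dend)
  expect_equal(merges$height[1], 0)
  expect_setequal(strsplit(merges$members[1], ",")[[1]], c("A", "B"))
  expect_equal(merges$height[2], 0.6) # d(A,C) = d(B,C) = 2+4 of 10
  expect_error(cluster_missingness(d[1, 1, drop = FALSE]), "at least 2")
})

test_that("planted missingness blocks merge below every cross-block merge", {
  st <- default_study()
  bundle <- default_bundle()
  dend <- bundle$missingness$dendrogram
  merges <- dendrogram_merges(dend)
  d <- bundle$missingness$discordance
  for (block in st$truth$missing_blocks) {
    inside <- intersect(block, colnames(d))
    within_max <- max(d[inside, inside])
    others <- setdiff(colnames(d), inside)
    cross_min <- min(d[inside, others])
    expect_lt(within_max, cross_min)
    # the block becomes a cluster before any of its members joins an outsider
    first_with_all <- which(vapply(strsplit(merges$members, ","), function(m) {
      all(inside %in% m)
    }, logical(1)))[1]
    expect_setequal(
      setdiff(strsplit(merges$members[first_with_all], ",")[[1]], inside),
      character(0)
    )
  }
})

test_that("complete-vs-incomplete contrasts recover a planted age dependence", {
  spec <- default_bacteremia_like_spec(seed = 21, n_rows = 1500)
  spec$missing_age_shift <- list(var = "CRP", shift = 1.5)
  st <- generate_synthetic_study(spec)
  contrasts <- compare_missingness_groups(st$data, "CRP", st$dictionary)
  smd_age <- contrasts$std_difference[contrasts$variable == "AGE"]
  expect_lt(smd_age, -0.3) # complete cases are younger when missingness rises with age

  # MCAR data: standardized differences near zero
  st0 <- default_study(n_rows = 1500, seed = 22)
  c0 <- compare_missingness_groups(st0$data, "CRP", st0$dictionary)
  expect_lt(abs(c0$std_difference[c0$variable == "AGE"]), 0.15)

  # degenerate split
  ds_full <- as_toy_dataset(toy_data(10))
  c_deg <- compare_missingness_groups(ds_full, c("A", "B"), toy_dict())
  expect_true(attr(c_deg, "degenerate"))
  expect_equal(nrow(c_deg), 0L)
})

test_that("dendrograms serialize to Newick with merge-height branch lengths", {
  bundle <- default_bundle()
  nwk <- dendrogram_newick(bundle$missingness$dendrogram)
  expect_match(nwk, "^\\(.*\\);$")
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, bundle$missingness$dendrogram$labels)
})
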