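test_that("rank correlation anchors: self, monotone transform, hand-computed ties", {
  dat <- toy_data(50)
  dat$B <- pseudolog(dat$C)
  ds <- as_toy_dataset(dat)
  S <- spearman_matrix(ds, c("C", "B"), toy_dict())
  expect_equal(S$r["C", "B"], 1)

  # 6-point table with a tie: brute force = Pearson on average ranks
  dat6 <- toy_data(6)
  dat6$A <- c(1, 2, 2, 4, 5, 6)
  dat6$B <- c(3, 1, 4, 4, 6, 5)
  S6 <- spearman_matrix(as_toy_dataset(dat6), c("A", "B"), toy_dict())
  brute <- cor(rank(dat6$A), rank(dat6$B))
  expect_equal(S6$r["A", "B"], brute)
})

test_that("product-moment anchors and Monte-Carlo recovery", {
  dat <- toy_data(40)
  dat$B <- 2 * dat$A + 1
  dat$C <- -dat$A
  ds <- as_toy_dataset(dat)
  P <- pearson_matrix(ds, c("A", "B", "C"), toy_dict())
  expect_equal(P$r["A", "B"], 1)
  expect_equal(P$r["A", "C"], -1)

  withr::with_seed(14, {
    n <- 10000
    z <- rnorm(n)
    datn <- toy_data(10)[rep(1, n), ]
    datn$A <- z
    datn$B <- 0.5 * z + sqrt(1 - 0.25) * rnorm(n)
  })
  Pn <- pearson_matrix(as_toy_dataset(datn), c("A", "B"), toy_dict())
  expect_lt(abs(Pn$r["A", "B"] - 0.5), 3 / sqrt(n))
})

test_that("pairwise-complete matrices equal complete-case matrices without missing data", {
  st <- default_study(n_rows = 300)
  vars <- c("WBC", "BUN", "CREA", "PLT")
  sub <- st$data[complete.cases(st$data[, vars]), ]
  S_pair <- spearman_matrix(sub, vars, st$dictionary) # pairwise-complete estimator
  direct <- cor(as.matrix(sub[, vars]), method = "spearman") # complete-case oracle
  expect_equal(S_pair$r, direct)
  expect_true(all(S_pair$n_pairs == nrow(sub)))
  expect_true(all(S_pair$unreliable == (S_pair$n_pairs < 30)))
})

test_that("discrepancy screen flags outlier-driven divergence only", {
  st <- default_study(n_rows = 300)
  vars <- c("BUN", "CREA", "PLT", "POTASS")
  S <- spearman_matrix(st$data, vars, st$dictionary)
  P <- pearson_matrix(st$data, vars, st$dictionary)
  expect_equal(nrow(correlation_discrepancies(S, S, 0.1)), 0L)

  # plant one extreme point that drags Pearson far above Spearman
  dat <- toy_data(60)
  withr::with_seed(16, {
    dat$A <- rnorm(60)
    dat$B <- rnorm(60)
  })
  dat$A[60] <- 60
  dat$B[60] <- 60
  ds <- as_toy_dataset(dat)
  S2 <- spearman_matrix(ds, c("A", "B", "C"), toy_dict(), min_pairs = 10)
  P2 <- pearson_matrix(ds, c("A", "B", "C"), toy_dict(), min_pairs = 10)
  disc <- correlation_discrepancies(S2, P2, 0.1)
  expect_true(nrow(disc) >= 1L)
  expect_equal(c(disc$var1[1], disc$var2[1]), c("A", "B"))
  expect_equal(attr(disc, "n_pairs_total"), 3L)
})

test_that("structural associations: perfect, independent, and stratified", {
  st <- default_study(n_rows = 400)
  dat <- st$data
  dat$BUN <- dat$AGE # predictor identical to age
  tab <- structural_association_table(dat, st$dictionary, st$plan)
  bun <- tab[tab$predictor == "BUN", ]
  expect_true(all(abs(bun$spearman - 1) < 1e-12))
  # strata are the sex levels
  expect_setequal(unique(tab$stratum), c("1", "2"))
  # an independent lab correlates with age only at Monte-Carlo noise level
  sodium <- tab[tab$predictor == "SODIUM", ]
  expect_true(all(abs(sodium$spearman) < 3 / sqrt(pmax(sodium$n_pairs, 2)) + 0.05))
})

test_that("interaction screen: sparsity grid shape follows dependence", {
  n <- 1600
  withr::with_seed(17, {
    dat <- toy_data(n)
    dat$A <- rnorm(n)
    dat$B <- rnorm(n)
    dat$C <- dat$A
  })
  ds <- as_toy_dataset(dat)
  indep <- interaction_screen(ds, ida_plan(interactions = list(c("A", "B"))), toy_dict())[[1]]
  expect_equal(dim(indep$grid), c(4L, 4L))
  expect_true(all(abs(indep$grid - n / 16) < 5 * sqrt(n / 16)))

  perfect <- interaction_screen(ds, ida_plan(interactions = list(c("A", "C"))), toy_dict())[[1]]
  expect_equal(sum(diag(perfect$grid)), perfect$n_complete)
  expect_equal(perfect$spearman, 1)

  expect_length(interaction_screen(ds, ida_plan(), toy_dict()), 0L)
})

test_that("variable clustering lists planted high-correlation pairs and recovers blocks", {
  bundle <- default_bundle()
  pairs <- bundle$multivariate$clusters$high_corr_pairs
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  listed <- key(pairs$var1, pairs$var2)
  expect_true(key("RBC", "HGB") %in% listed) # planted Spearman 0.92
  expect_true(key("WBC", "NEU") %in% listed) # whole vs largest component
  expect_false(key("SODIUM", "CA") %in% listed) # independent labs stay out

  # block-diagonal structure: clustering recovers the planted blocks exactly
  withr::with_seed(18, {
    n <- 500
    make_block <- function(k) {
      z <- rnorm(n)
      sapply(seq_len(k), function(i) 0.95 * z + sqrt(1 - 0.95^2) * rnorm(n))
    }
    X <- cbind(make_block(3), make_block(3))
    colnames(X) <- paste0("V", 1:6)
    dat <- dplyr::bind_cols(toy_data(n)[, c("ID", "Y", "AGE", "SEX")], as.data.frame(X))
  })
  dict <- toy_dict(extra = tibble::tibble(
    name = paste0("V", 1:6), label = NA, scale = "continuous", units = NA,
    role = "minor", lower = NA_real_, upper = NA_real_,
    component_of = NA_character_, ratio_of = NA_character_
  ))
  dict <- dict[dict$name %in% c("ID", "Y", "AGE", "SEX", paste0("V", 1:6)), ]
  S <- spearman_matrix(as_toy_dataset(dat), paste0("V", 1:6), dict)
  vc <- variable_clusters(S, ida_plan())
  cl <- cutree(vc$dendrogram$hclust, k = 2)
  planted <- rep(1:2, each = 3)
  expect_true(mclust::adjustedRandIndex(cl[paste0("V", 1:6)], planted) == 1)
})

test_that("VIF matches the two-variable closed form across a correlation grid", {
  dict <- toy_dict()
  plan <- ida_plan()
  withr::with_seed(19, {
    for (r_target in c(0, 0.3, 0.6, 0.9, 0.99)) {
      n <- 400
      dat <- toy_data(n)
      z <- rnorm(n)
      dat$A <- z
      dat$B <- r_target * z + sqrt(1 - r_target^2) * rnorm(n)
      ds <- as_toy_dataset(dat)
      res <- vif(ds, c("A", "B"), dict, plan, basis = "linear")
      r_emp <- cor(dat$A, dat$B)
      expect_equal(res$table$vif, rep(1 / (1 - r_emp^2), 2), tolerance = 1e-9)
    }
  })
})

test_that("independent predictors have VIF near 1; a duplicate goes infinite", {
  n <- 500
  withr::with_seed(20, {
    dat <- toy_data(n)
    dat$A <- rnorm(n)
    dat$B <- rnorm(n)
    dat$C <- rnorm(n)
  })
  ds <- as_toy_dataset(dat)
  res <- vif(ds, c("A", "B", "C"), toy_dict(), ida_plan())
  expect_true(all(abs(res$table$vif - 1) < 0.1))

  dat$C <- dat$A # exact copy: singular system
  res2 <- vif(as_toy_dataset(dat), c("A", "B", "C"), toy_dict(), ida_plan())
  expect_true(any(res2$table$infinite))
  expect_error(
    vif(as_toy_dataset(dat[1:3, ]), c("A", "B", "C"), toy_dict(), ida_plan()),
    "complete cases"
  )
})

test_that("additive-basis generalized VIF agrees with the standard determinant oracle", {
  n <- 400
  withr::with_seed(23, {
    dat <- toy_data(n)
    z <- rnorm(n)
    dat$A <- z + rnorm(n, sd = 0.6)
    dat$B <- z + rnorm(n, sd = 0.6)
    dat$C <- rnorm(n)
  })
  ds <- as_toy_dataset(dat)
  dict <- toy_dict()
  res <- vif(ds, c("A", "B", "C"), dict, ida_plan(), basis = "additive")
  # oracle: car computes generalized VIFs from the same grouped design,
  # via a dummy response (GVIF depends only on the design)
  blocks <- lapply(c("A", "B", "C"), function(v) {
    idascreen:::predictor_columns(ds, v, dict, "additive")
  })
  df <- data.frame(
    y = withr::with_seed(1, rnorm(n)),
    Ab = I(blocks[[1]]), Bb = I(blocks[[2]]), Cb = I(blocks[[3]])
  )
  fit <- lm(y ~ Ab + Bb + Cb, data = df)
  gv <- car::vif(fit)
  expect_equal(res$table$vif, unname(gv[, "GVIF"]), tolerance = 1e-8)
  expect_equal(res$table$df, unname(gv[, "Df"]))
  expect_equal(
    res$table$vif_scaled,
    unname(gv[, 3]^2), # car reports GVIF^(1/(2 Df))
    tolerance = 1e-8
  )
})

test_that("redundancy analysis removes duplicates and spares independent sets", {
  n <- 300
  withr::with_seed(24, {
    dat <- toy_data(n)
    dat$A <- rnorm(n)
    dat$B <- rnorm(n)
    dat$C <- dat$A # exact copy
  })
  res <- redundancy_analysis(as_toy_dataset(dat), c("A", "B", "C"), toy_dict(), ida_plan())
  expect_equal(nrow(res$removal_sequence), 1L)
  expect_true(res$removal_sequence$variable %in% c("A", "C"))
  expect_equal(res$removal_sequence$r_squared, 1, tolerance = 1e-9)

  dat$C <- rnorm(n)
  res2 <- redundancy_analysis(as_toy_dataset(dat), c("A", "B", "C"), toy_dict(), ida_plan())
  expect_equal(nrow(res2$removal_sequence), 0L)
})

test_that("the composition block shows high VIF while independent labs stay near 1", {
  bundle <- default_bundle()
  key_vif <- bundle$multivariate$vif$key$linear$table
  expect_gt(max(key_vif$vif[key_vif$variable %in% c("WBC", "NEU")]), 5)
  expect_lt(max(key_vif$vif[key_vif$variable %in% c("BUN", "CREA", "PLT")]), 1.5)
  red <- bundle$multivariate$redundancy$key
  expect_false(is.character(red))
  expect_true(max(red$r_squared[c("WBC", "NEU")]) > 0.8)
})
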