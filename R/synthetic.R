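# Internal: make a plain tibble behave like a dataset read from disk.
as_ida_dataset <- function(tbl, dict) {
  attr(tbl, "limit_violations") <- tibble(variable = names(tbl), n_violations = 0L)
  attr(tbl, "n_rows") <- nrow(tbl)
  class(tbl) <- unique(c("ida_dataset", class(tbl)))
  tbl
}

#' Specification of a synthetic clinical-laboratory study
#'
#' Describes a dataset generator that emulates the structure of routine
#' laboratory data collected for a binary diagnostic outcome: heavily
#' right-skewed (lognormal) concentrations, a part-whole cell-count block
#' (a total count that is approximately - but not exactly - the sum of its
#' component counts) with derived percentage ("ratio") variables,
#' spike-at-zero components, block-correlated missingness, and an outcome
#' drawn independently of all predictors at a fixed prevalence (so that
#' screening has nothing to leak).
#'
#' @param n_rows Number of observations.
#' @param prevalence Outcome prevalence.
#' @param labs Tibble `name`, `meanlog`, `sdlog` of lognormal lab variables.
#' @param composition List: `whole` (name), `components` (names), `shares`
#'   (positive, summing to ~1), `component_noise_sd`, `whole_noise_sd`
#'   (lognormal noise sds), `total_meanlog`, `total_sdlog`.
#' @param ratios Named character vector: ratio-variable name -> component
#'   name (percentage of the component sum).
#' @param spikes Named numeric: component/lab name -> zero-inflation
#'   probability.
#' @param missing_blocks List of lists `vars`, `p` (members share one
#'   missing indicator with probability `p`) - block-correlated
#'   missingness.
#' @param missing_individual Named numeric: per-variable independent
#'   missingness probabilities (added on top of any block indicator).
#' @param missing_age_shift Optional list `var`, `shift`: logistic
#'   dependence of that variable's missingness on standardized age.
#' @param correlation_plants Tibble `var1`, `var2`, `rho` of target
#'   Spearman correlations realized through a Gaussian copula on latent
#'   normals (latent correlation `2 sin(pi rho / 6)`).
#' @param outcome_effect Optional list `var`, `beta`: plants a logistic
#'   effect of the standardized (log) predictor on the outcome - only used
#'   to test that blinding destroys it.
#' @param seed Integer seed.
#' @return A list of class `ida_synthetic_spec`.
#' @export
synthetic_spec <- function(n_rows, prevalence, labs, composition, ratios,
                           spikes = numeric(), missing_blocks = list(),
                           missing_individual = numeric(),
                           missing_age_shift = NULL,
                           correlation_plants = tibble(var1 = character(), var2 = character(), rho = numeric()),
                           outcome_effect = NULL, seed = 1L) {
  all_names <- c(labs$name, composition$whole, composition$components, names(ratios))
  if (anyDuplicated(all_names)) abort("Synthetic variable names must be unique.")
  if (prevalence <= 0 || prevalence >= 1) abort("Prevalence must lie in (0, 1).")
  if (any(composition$shares <= 0)) abort("Composition shares must be positive.")
  if (length(spikes) && (any(spikes < 0) || any(spikes > 1))) {
    abort("Spike probabilities must lie in [0, 1].")
  }
  if (nrow(correlation_plants)) {
    planted <- c(correlation_plants$var1, correlation_plants$var2)
    if (any(abs(correlation_plants$rho) >= 1)) {
      bad <- correlation_plants[abs(correlation_plants$rho) >= 1, ][1, ]
      abort(sprintf("Infeasible correlation plant for pair (%s, %s).", bad$var1, bad$var2))
    }
    if (anyDuplicated(planted)) {
      abort(sprintf(
        "Infeasible correlation plant: variable %s appears in more than one pair.",
        planted[duplicated(planted)][1]
      ))
    }
    in_comp <- intersect(planted, c(composition$whole, composition$components, names(ratios)))
    if (length(in_comp)) {
      abort(sprintf(
        "Infeasible correlation plant: %s belongs to the composition block.",
        in_comp[1]
      ))
    }
  }
  structure(
    list(
      n_rows = as.integer(n_rows), prevalence = prevalence, labs = labs,
      composition = composition, ratios = ratios, spikes = spikes,
      missing_blocks = missing_blocks, missing_individual = missing_individual,
      missing_age_shift = missing_age_shift,
      correlation_plants = correlation_plants,
      outcome_effect = outcome_effect,
      seed = stopifnot_scalar_int(seed, "seed")
    ),
    class = "ida_synthetic_spec"
  )
}

#' Default bacteremia-like synthetic specification
#'
#' A 51-predictor study mirroring the structure of a routine-laboratory
#' diagnostic dataset: two structural variables (age, sex), a 5-component
#' leukocyte block (neutrophils the dominant component of the white blood
#' count) with percentage variables, zero-spiked basophil/eosinophil
#' analogues (87% and 48% zeros), 38 lognormal labs of which 15 are
#' strongly skewed (log-sd at least 1), block-correlated missingness
#' mimicking lipid/pancreas and coagulation panels plus two individually
#' missing variables above 20%, one planted high rank correlation between
#' red-cell measures, and an 8% binary outcome independent of all
#' predictors.
#'
#' @param seed Integer seed.
#' @param n_rows Number of observations (default 2000).
#' @param outcome_effect Optional planted logistic outcome effect (see
#'   [synthetic_spec()]); off by default so the fixture honours the
#'   no-association principle.
#' @return An `ida_synthetic_spec`.
#' @export
default_bacteremia_like_spec <- function(seed = 1L, n_rows = 2000L, outcome_effect = NULL) {
  skewed <- c(
    CRP = 1.3, GGT = 1.2, ASAT = 1.1, ALAT = 1.2, TRIG = 1.15, PAMY = 1.3,
    CK = 1.4, GBIL = 1.2, LDH = 1.1, AMY = 1.1, LIP = 1.3, AP = 1.15,
    HS = 1.2, BUN = 1.1, CREA = 1.1
  )
  mild <- c(
    PLT = 0.45, POTASS = 0.12, FIB = 0.35, GLU = 0.35, CHOL = 0.3,
    RBC = 0.15, HGB = 0.15, HCT = 0.15, MCH = 0.06, MCHC = 0.04,
    MCV = 0.06, MPV = 0.12, PDW = 0.18, RDW = 0.12, NT = 0.25,
    APTT = 0.2, ALB = 0.12, CA = 0.07, CHE = 0.3, MG = 0.1,
    PHOS = 0.25, SODIUM = 0.03, TP = 0.08
  )
  typical <- c(
    CRP = 8, GGT = 40, ASAT = 30, ALAT = 28, TRIG = 120, PAMY = 30,
    CK = 90, GBIL = 12, LDH = 220, AMY = 60, LIP = 40, AP = 80,
    HS = 25, BUN = 18, CREA = 12,
    PLT = 230, POTASS = 4.1, FIB = 400, GLU = 110, CHOL = 180,
    RBC = 4.4, HGB = 130, HCT = 39, MCH = 30, MCHC = 33, MCV = 89,
    MPV = 10.5, PDW = 12, RDW = 14, NT = 90, APTT = 35, ALB = 40,
    CA = 2.3, CHE = 7, MG = 0.85, PHOS = 1.1, SODIUM = 139, TP = 70
  )
  sdlogs <- c(skewed, mild)
  labs <- tibble(
    name = names(sdlogs),
    meanlog = log(typical[names(sdlogs)]),
    sdlog = unname(sdlogs)
  )
  synthetic_spec(
    n_rows = n_rows,
    prevalence = 0.08,
    labs = labs,
    composition = list(
      whole = "WBC",
      components = c("NEU", "LYM", "MONO", "EOS", "BASO"),
      shares = c(0.60, 0.25, 0.08, 0.04, 0.03),
      component_noise_sd = 0.25,
      whole_noise_sd = 0.02,
      total_meanlog = log(8.5),
      total_sdlog = 0.45
    ),
    ratios = c(NEUR = "NEU", LYMR = "LYM", MONOR = "MONO", EOSR = "EOS", BASOR = "BASO"),
    spikes = c(BASO = 0.87, EOS = 0.48),
    missing_blocks = list(
      list(vars = c("TRIG", "CHOL", "PAMY"), p = 0.35),
      list(vars = c("AMY", "LIP"), p = 0.22),
      list(vars = c("FIB", "NT", "APTT"), p = 0.12)
    ),
    missing_individual = c(
      # individually missing panels above the review threshold
      GLU = 0.25, HS = 0.22,
      # small independent extras inside the blocks (keeps within-block
      # discordance positive but far below the block threshold)
      TRIG = 0.01, CHOL = 0.01, PAMY = 0.01, AMY = 0.01, LIP = 0.01,
      FIB = 0.01, NT = 0.01, APTT = 0.01,
      # mid-band panels (10-20%)
      CRP = 0.12, GGT = 0.12, CK = 0.12, GBIL = 0.12, LDH = 0.11,
      CHE = 0.12, PHOS = 0.11,
      # everything else loses only a few percent; key labs stay nearly complete
      ASAT = 0.04, ALAT = 0.04, AP = 0.06, MG = 0.05, ALB = 0.03,
      BUN = 0.01, CREA = 0.01, PLT = 0.01, POTASS = 0.02,
      WBC = 0.01, NEU = 0.02, LYM = 0.03, MONO = 0.03, EOS = 0.03, BASO = 0.03,
      NEUR = 0.03, LYMR = 0.03, MONOR = 0.03, EOSR = 0.03, BASOR = 0.03
    ),
    correlation_plants = tibble(var1 = "RBC", var2 = "HGB", rho = 0.92),
    outcome_effect = outcome_effect,
    seed = seed
  )
}

spearman_to_latent <- function(rho) 2 * sin(pi * rho / 6)

#' Generate a synthetic study from a specification
#'
#' Draws the dataset, builds the matching data dictionary (roles, scales,
#' part-whole and ratio relations) and default plan, and records the
#' ground truth of every planted feature for oracle testing. Identical
#' spec and seed give the identical dataset.
#'
#' @param spec An `ida_synthetic_spec`.
#' @return List with `dictionary` (`ida_dictionary`), `data`
#'   (`ida_dataset`), `plan` (`ida_plan`) and `truth` (list: expected
#'   missing proportions, planted blocks, spike probabilities, lognormal
#'   log-sds, correlation plants with latent correlations, composition,
#'   prevalence, outcome effect).
#' @export
generate_synthetic_study <- function(spec) {
  n <- spec$n_rows
  with_seed(spec$seed, {
    age <- pmin(pmax(round(rnorm(n, 60, 15)), 16), 100)
    sex <- ifelse(runif(n) < 0.55, "1", "2")

    # lognormal labs, correlation plants via Gaussian copula
    lab_vals <- list()
    planted <- spec$correlation_plants
    plant_members <- c(planted$var1, planted$var2)
    for (i in seq_len(nrow(spec$labs))) {
      nm <- spec$labs$name[i]
      if (nm %in% plant_members) next
      lab_vals[[nm]] <- rlnorm(n, spec$labs$meanlog[i], spec$labs$sdlog[i])
    }
    latent_r <- numeric(0)
    for (i in seq_len(nrow(planted))) {
      v1 <- planted$var1[i]
      v2 <- planted$var2[i]
      r <- spearman_to_latent(planted$rho[i])
      latent_r <- c(latent_r, r)
      z1 <- rnorm(n)
      z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n)
      p1 <- spec$labs[spec$labs$name == v1, ]
      p2 <- spec$labs[spec$labs$name == v2, ]
      lab_vals[[v1]] <- exp(p1$meanlog + p1$sdlog * z1)
      lab_vals[[v2]] <- exp(p2$meanlog + p2$sdlog * z2)
    }

    # part-whole composition block
    comp <- spec$composition
    total <- rlnorm(n, comp$total_meanlog, comp$total_sdlog)
    k <- length(comp$components)
    share_noise <- matrix(exp(rnorm(n * k, 0, comp$component_noise_sd)), n, k)
    shares <- matrix(comp$shares, n, k, byrow = TRUE) * share_noise
    shares <- shares / rowSums(shares)
    components <- shares * total
    colnames(components) <- comp$components
    # zero spikes imposed before ratios
    for (nm in names(spec$spikes)) {
      if (nm %in% comp$components) {
        components[, nm] <- components[, nm] * (runif(n) >= spec$spikes[[nm]])
      } else if (nm %in% names(lab_vals)) {
        lab_vals[[nm]] <- lab_vals[[nm]] * (runif(n) >= spec$spikes[[nm]])
      }
    }
    comp_sum <- rowSums(components)
    whole <- comp_sum * exp(rnorm(n, 0, comp$whole_noise_sd))
    ratio_vals <- lapply(spec$ratios, function(src) 100 * components[, src] / comp_sum)
    names(ratio_vals) <- names(spec$ratios)

    values <- c(
      list(AGE = age),
      setNames(list(whole), comp$whole),
      as.list(as.data.frame(components)),
      ratio_vals,
      lab_vals
    )
    values <- lapply(values, function(x) round(x, 4))
    values$AGE <- age

    # outcome: independent of predictors unless an effect is planted
    if (is.null(spec$outcome_effect)) {
      outcome <- ifelse(runif(n) < spec$prevalence, "yes", "no")
    } else {
      x <- log(values[[spec$outcome_effect$var]] + 1)
      eta <- qlogis(spec$prevalence) + spec$outcome_effect$beta * as.numeric(scale(x))
      outcome <- ifelse(runif(n) < plogis(eta), "yes", "no")
    }

    # missingness imposed last: shared block indicators + independent extras
    miss_prob_extra <- spec$missing_individual
    miss <- lapply(values, function(x) rep(FALSE, n))
    for (b in spec$missing_blocks) {
      ind <- runif(n) < b$p
      for (v in b$vars) miss[[v]] <- miss[[v]] | ind
    }
    for (v in names(miss_prob_extra)) {
      if (!v %in% names(miss)) next
      miss[[v]] <- miss[[v]] | (runif(n) < miss_prob_extra[[v]])
    }
    if (!is.null(spec$missing_age_shift)) {
      v <- spec$missing_age_shift$var
      eta <- qlogis(miss_prob_extra[[v]] %||% 0.1) +
        spec$missing_age_shift$shift * as.numeric(scale(age))
      miss[[v]] <- miss[[v]] | (runif(n) < plogis(eta))
    }
    for (v in names(values)) {
      if (v == "AGE") next # structural variables stay complete
      values[[v]][miss[[v]]] <- NA
    }

    data <- dplyr::bind_cols(
      tibble(ID = as.character(seq_len(n)), BloodCulture = outcome, SEX = sex),
      as_tibble(values)
    )
  })

  dict <- synthetic_dictionary(spec)
  data <- data[, dict$name]
  data <- as_ida_dataset(data, dict)

  # expected total missingness per variable under the planted mechanism
  block_p <- setNames(rep(0, length(names(data))), names(data))
  for (b in spec$missing_blocks) block_p[b$vars] <- 1 - (1 - block_p[b$vars]) * (1 - b$p)
  for (v in names(spec$missing_individual)) {
    if (v %in% names(block_p)) {
      block_p[v] <- 1 - (1 - block_p[v]) * (1 - spec$missing_individual[[v]])
    }
  }
  truth <- list(
    missing = tibble(variable = names(block_p), proportion = unname(block_p)),
    missing_blocks = lapply(spec$missing_blocks, function(b) b$vars),
    spikes = spec$spikes,
    lognormal_sigma = setNames(spec$labs$sdlog, spec$labs$name),
    correlation_plants = dplyr::mutate(
      spec$correlation_plants,
      latent_r = spearman_to_latent(.data$rho)
    ),
    composition = spec$composition,
    prevalence = spec$prevalence,
    outcome_effect = spec$outcome_effect,
    seed = spec$seed
  )
  list(
    dictionary = dict, data = data,
    plan = synthetic_default_plan(spec, dict), truth = truth
  )
}

synthetic_dictionary <- function(spec) {
  comp <- spec$composition
  key <- c("WBC", "NEU", "BUN", "CREA", "PLT")
  medium <- c("POTASS", "FIB", "CRP", "ASAT", "ALAT", "GGT")
  ratio_src <- spec$ratios
  rows <- list(
    tibble(name = "ID", label = "Identifier", scale = "nominal", role = "identifier"),
    tibble(name = "BloodCulture", label = "Blood culture result", scale = "binary", role = "outcome"),
    tibble(name = "AGE", label = "Age", scale = "continuous", role = "structural"),
    tibble(name = "SEX", label = "Sex", scale = "nominal", role = "structural"),
    tibble(
      name = comp$whole, label = "Total leukocyte-like count",
      scale = "continuous", role = if (comp$whole %in% key) "key" else "minor"
    ),
    tibble(
      name = comp$components,
      label = paste("Component of", comp$whole),
      scale = "continuous",
      role = ifelse(comp$components %in% key, "key", "minor"),
      component_of = comp$whole
    ),
    tibble(
      name = names(ratio_src),
      label = paste("Percentage form of", unname(ratio_src)),
      scale = "continuous", role = "minor",
      ratio_of = unname(ratio_src)
    ),
    tibble(
      name = spec$labs$name, label = "Lab measurement", scale = "continuous",
      role = dplyr::case_when(
        spec$labs$name %in% key ~ "key",
        spec$labs$name %in% medium ~ "medium",
        TRUE ~ "minor"
      )
    )
  )
  dict <- dplyr::bind_rows(rows)
  dict$units <- NA_character_
  dict$lower <- NA_real_
  dict$upper <- NA_real_
  if (!"component_of" %in% names(dict)) dict$component_of <- NA_character_
  if (!"ratio_of" %in% names(dict)) dict$ratio_of <- NA_character_
  dict$collapse_map <- vector("list", nrow(dict))
  dict <- dict[, c(
    "name", "label", "scale", "units", "role", "lower", "upper",
    "component_of", "ratio_of", "collapse_map"
  )]
  validate_dictionary(dict)
  class(dict) <- unique(c("ida_dictionary", "tbl_df", "tbl", "data.frame"))
  dict
}

synthetic_default_plan <- function(spec, dict) {
  structural <- dict$name[dict$role == "structural"]
  key <- dict$name[dict$role == "key"]
  medium <- dict$name[dict$role == "medium"]
  all_pred <- predictor_variables(dict)
  ida_plan(
    model_sets = list(
      structural = structural,
      key = c(structural, key),
      key_medium = c(structural, key, medium),
      all = all_pred
    ),
    interactions = list(c("AGE", "BUN")),
    seed = spec$seed
  )
}

#' Write a synthetic study to disk
#'
#' Writes the data, dictionary, plan and ground-truth JSON of a generated
#' study into a directory, ready for [run_ida()].
#'
#' @param study Output of [generate_synthetic_study()].
#' @param dir Output directory.
#' @return The directory path, invisibly.
#' @export
write_synthetic_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_dataset(study$data, file.path(dir, "data.csv"))
  write_data_dictionary(study$dictionary, file.path(dir, "dictionary.csv"))
  write_ida_plan(study$plan, file.path(dir, "plan.yaml"))
  truth <- study$truth
  truth$missing <- as.data.frame(truth$missing)
  truth$correlation_plants <- as.data.frame(truth$correlation_plants)
  writeLines(
    as.character(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA, null = "null")),
    file.path(dir, "ground_truth.json")
  )
  invisible(dir)
}
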