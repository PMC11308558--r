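#' Quantile presets for univariate summaries
#'
#' Two conventional probability sets for reporting continuous variables:
#' `main` (5th, 10th, 25th, 50th, 75th, 90th, 95th) and `tails`
#' (1st, 5th, 25th, 50th, 75th, 90th, 99th).
#'
#' @export
ida_quantile_presets <- list(
  main = c(0.05, 0.10, 0.25, 0.50, 0.75, 0.90, 0.95),
  tails = c(0.01, 0.05, 0.25, 0.50, 0.75, 0.90, 0.99)
)

default_thresholds <- function() {
  list(
    spearman_pearson_delta = 0.1, # flag pairs whose rank vs product-moment correlation differ more
    high_corr = 0.8, # Spearman above this lists a pair for scatter review
    normdev_gain = 0.2, # minimum gain in normal-scores correlation to adopt a transform
    missing_review = 0.20, # item-missingness proportion triggering review
    missing_omit = 1 / 3, # item-missingness proportion triggering omission candidacy
    spike_mode_prop = 0.40, # modal proportion at/above which a spike is flagged
    vif_flag = 5, # variance inflation factor worth flagging
    redundancy_r2 = 0.9, # additive-model R-squared above which a predictor is redundant
    block_discordance = 0.05, # max pairwise discordance within a correlated-missingness block
    min_level_count = 10 # categorical level count below which collapsing is suggested
  )
}

#' Construct a screening plan
#'
#' The plan holds everything the screening run needs besides the data and
#' dictionary: the candidate predictor sets, declared interactions, decision
#' thresholds, quantile set, pseudo-log settings, stratification rule for
#' continuous structural variables, minimum pairwise-complete sample size
#' for correlations, and the seed.
#'
#' @param model_sets Named list of character vectors of predictor names,
#'   ordered from smallest to largest candidate model (e.g. structural, key,
#'   key+medium, all).
#' @param interactions List of length-2 character vectors: predictor pairs
#'   whose joint distribution should be screened.
#' @param thresholds Named list overriding any of the default decision
#'   thresholds; see Details.
#' @param quantiles Probabilities for univariate quantile summaries
#'   (default `ida_quantile_presets$main`), strictly increasing in (0, 1).
#' @param pseudolog List with `sigma` (global scale, default 1),
#'   `sigma_by_variable` (named overrides) and `base` (default 10).
#' @param structural_strata Binning rule for continuous structural
#'   variables: `"decades"` (default) or a bin width.
#' @param seed Integer seed governing all randomness (blinding permutation).
#' @param min_pairs Minimum pairwise-complete observations for a
#'   correlation entry to be considered reliable (default 30).
#'
#' @details Default thresholds: Spearman/Pearson discrepancy 0.1;
#' high-correlation listing 0.8; normal-scores-correlation gain 0.2 for
#' adopting a transformation; missingness review 0.20 and omission 1/3;
#' spike modal proportion 0.40; VIF flag 5; redundancy R-squared 0.9;
#' within-block missingness discordance 0.05; minimum category count 10.
#'
#' @return A list of class `ida_plan`.
#' @export
ida_plan <- function(model_sets = list(),
                     interactions = list(),
                     thresholds = list(),
                     quantiles = ida_quantile_presets$main,
                     pseudolog = list(),
                     structural_strata = "decades",
                     seed = 1L,
                     min_pairs = 30L) {
  th <- utils::modifyList(default_thresholds(), thresholds)
  props <- c(
    "spearman_pearson_delta", "high_corr", "missing_review", "missing_omit",
    "spike_mode_prop", "redundancy_r2", "block_discordance"
  )
  for (p in props) {
    if (th[[p]] <= 0 || th[[p]] >= 1) {
      abort(sprintf("Threshold `%s` must lie in (0, 1).", p))
    }
  }
  if (any(diff(quantiles) <= 0) || any(quantiles <= 0) || any(quantiles >= 1)) {
    abort("`quantiles` must be strictly increasing within (0, 1).")
  }
  pl <- utils::modifyList(
    list(sigma = 1, sigma_by_variable = list(), base = 10),
    pseudolog
  )
  if (pl$sigma <= 0) abort("pseudolog sigma must be positive.")
  if (pl$base <= 1) abort("pseudolog base must exceed 1.")
  structure(
    list(
      model_sets = model_sets,
      interactions = interactions,
      thresholds = th,
      quantiles = quantiles,
      pseudolog = pl,
      structural_strata = structural_strata,
      seed = stopifnot_scalar_int(seed, "seed"),
      min_pairs = as.integer(min_pairs)
    ),
    class = "ida_plan"
  )
}

#' Read a screening plan from a YAML file
#'
#' The file mirrors the [ida_plan()] fields exactly; absent fields take
#' their defaults.
#'
#' @param file Path to a YAML plan.
#' @return An `ida_plan`.
#' @export
read_ida_plan <- function(file) {
  y <- yaml::read_yaml(file)
  ida_plan(
    model_sets = lapply(y$model_sets %||% list(), unlist),
    interactions = lapply(y$interactions %||% list(), unlist),
    thresholds = y$thresholds %||% list(),
    quantiles = unlist(y$quantiles %||% ida_quantile_presets$main),
    pseudolog = y$pseudolog %||% list(),
    structural_strata = y$structural_strata %||% "decades",
    seed = y$seed %||% 1L,
    min_pairs = y$min_pairs %||% 30L
  )
}

#' Write a screening plan to YAML
#'
#' @param plan An `ida_plan`.
#' @param file Output path.
#' @export
write_ida_plan <- function(plan, file) {
  yaml::write_yaml(unclass(plan), file)
  invisible(file)
}

#' Cross-validate plan, dictionary and dataset
#'
#' Checks that the plan is executable against the data and dictionary.
#' Nothing is thrown; every issue becomes a report entry. Errors: a model-set
#' member absent from the data; no outcome column in the data; an
#' interaction pair whose members are not two distinct predictors present in
#' the data. Warnings: a structural variable with missing values; a model
#' set with fewer than two members.
#'
#' @param plan An `ida_plan`.
#' @param dict An `ida_dictionary`.
#' @param ds An `ida_dataset`.
#' @return A tibble of class `ida_validation` with columns `severity`
#'   (`"error"`/`"warning"`), `code`, `message`, `variable`. Zero rows means
#'   the plan is executable.
#' @export
validate_plan <- function(plan, dict, ds) {
  findings <- list()
  add <- function(severity, code, message, variable = NA_character_) {
    findings[[length(findings) + 1L]] <<- tibble(
      severity = severity, code = code, message = message, variable = variable
    )
  }
  outcome <- dict$name[dict$role == "outcome"]
  if (!outcome %in% names(ds)) {
    add("error", "NO_OUTCOME", sprintf("Outcome variable %s not present in the data.", outcome), outcome)
  }
  predictors <- predictor_variables(dict)
  for (set_name in names(plan$model_sets)) {
    members <- plan$model_sets[[set_name]]
    absent <- setdiff(members, names(ds))
    for (v in absent) {
      add("error", "SET_MEMBER_ABSENT", sprintf("Model set '%s' member %s absent from the data.", set_name, v), v)
    }
    if (length(members) < 2L) {
      add("warning", "SMALL_MODEL_SET", sprintf("Model set '%s' has fewer than 2 members.", set_name))
    }
  }
  for (pair in plan$interactions) {
    if (length(pair) != 2L || pair[1] == pair[2]) {
      add("error", "DEGENERATE_INTERACTION", sprintf("Interaction (%s) is not a pair of two distinct predictors.", paste(pair, collapse = ", ")))
      next
    }
    for (v in pair) {
      if (!v %in% predictors || !v %in% names(ds)) {
        add("error", "INTERACTION_NOT_PREDICTOR", sprintf("Interaction member %s is not a predictor present in the data.", v), v)
      }
    }
  }
  for (v in dict$name[dict$role == "structural"]) {
    if (v %in% names(ds) && anyNA(ds[[v]])) {
      add("warning", "STRUCTURAL_MISSING", sprintf("Structural variable %s has missing values.", v), v)
    }
  }
  out <- if (length(findings)) dplyr::bind_rows(findings) else {
    tibble(
      severity = character(), code = character(),
      message = character(), variable = character()
    )
  }
  class(out) <- unique(c("ida_validation", class(out)))
  out
}
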