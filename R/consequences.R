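#' Turn screening results into candidate analysis-plan amendments
#'
#' Deterministic, pre-specifiable rules mapping the screening bundle to
#' findings, each with a full evidence trail. Rules (all thresholds from
#' the plan, defaults in parentheses):
#' \describe{
#'   \item{SPIKE_DEGENERATE}{modal proportion at or above `spike_mode_prop`
#'     (0.40): a degenerate spike no transformation can remove; discard
#'     candidate.}
#'   \item{HIGH_MISSING_OMIT}{missingness proportion above `missing_omit`
#'     (1/3): omission candidate.}
#'   \item{HIGH_MISSING_REVIEW}{missingness proportion above
#'     `missing_review` (0.20) but not beyond the omission threshold:
#'     review.}
#'   \item{CORRELATED_MISSINGNESS_BLOCK}{two or more high-missingness
#'     variables whose pairwise missingness discordance stays below
#'     `block_discordance` (0.05): they cannot serve each other in
#'     imputation models; review.}
#'   \item{COLLINEAR_PAIR}{Spearman correlation above `high_corr` (0.8):
#'     review.}
#'   \item{PART_WHOLE_REPARAM}{a collinear pair whose members are linked by
#'     a part-whole (`component_of`) relation: recommends replacing the
#'     whole W by the derived difference W_NO<C> = W - C, which removes the
#'     built-in correlation while retaining all information.}
#'   \item{RATIO_REDUNDANT}{a derived-percentage (`ratio_of`) variable
#'     highly rank-correlated with its source: not needed alongside it.}
#'   \item{SPARSE_CATEGORY_COLLAPSE}{a categorical level with fewer than
#'     `min_level_count` (10) observations: suggest collapsing.}
#' }
#' No rule evaluates any predictor-outcome association; findings are
#' recommendations, never automatic drops.
#'
#' @param bundle An `ida_bundle` from [ida_screen()] (or a list with
#'   `missingness`, `univariate`, `multivariate` components).
#' @param dict An `ida_dictionary`.
#' @param plan An `ida_plan`.
#' @return Tibble of class `ida_findings`: `rule_id`, `variables`
#'   (list-column), `evidence` (list-column of named statistics, values
#'   taken verbatim from the bundle), `action`, `severity`
#'   (`discard_candidate` / `review` / `reparameterize`).
#' @export
apply_consequence_rules <- function(bundle, dict, plan) {
  th <- plan$thresholds
  rows <- list()
  add <- function(rule_id, variables, evidence, action, severity) {
    rows[[length(rows) + 1L]] <<- tibble(
      rule_id = rule_id, variables = list(variables),
      evidence = list(evidence), action = action, severity = severity
    )
  }

  # SPIKE_DEGENERATE
  spikes <- bundle$univariate$spikes
  for (s in spikes) {
    add(
      "SPIKE_DEGENERATE", s$variable,
      list(mode_value = s$mode_value, mode_proportion = s$mode_proportion, concentration_ratio = s$concentration_ratio),
      sprintf(
        "Consider discarding %s: %.0f%% of values equal %g; the spike cannot be removed by transformation.",
        s$variable, 100 * s$mode_proportion, s$mode_value
      ),
      "discard_candidate"
    )
  }

  # HIGH_MISSING_OMIT / HIGH_MISSING_REVIEW
  item <- bundle$missingness$item
  if (!is.null(item)) {
    pred <- item[item$role %in% c("key", "medium", "minor", "structural"), ]
    for (i in seq_len(nrow(pred))) {
      p <- pred$proportion[i]
      v <- pred$variable[i]
      if (p > th$missing_omit) {
        add(
          "HIGH_MISSING_OMIT", v, list(missing_proportion = p),
          sprintf("Consider omitting %s: %.0f%% of its values are missing.", v, 100 * p),
          "discard_candidate"
        )
      } else if (p > th$missing_review) {
        add(
          "HIGH_MISSING_REVIEW", v, list(missing_proportion = p),
          sprintf("Review %s: %.0f%% of its values are missing.", v, 100 * p),
          "review"
        )
      }
    }
  }

  # CORRELATED_MISSINGNESS_BLOCK: connected components of high-missingness
  # variables under "discordance < block_discordance"
  d <- bundle$missingness$discordance
  if (!is.null(d) && !is.null(item)) {
    high <- item$variable[item$proportion > th$missing_review &
      item$variable %in% colnames(d)]
    if (length(high) >= 2L) {
      sub <- d[high, high, drop = FALSE]
      adj <- sub < th$block_discordance
      comp <- components_of(adj)
      for (grp in comp) {
        if (length(grp) >= 2L) {
          add(
            "CORRELATED_MISSINGNESS_BLOCK", grp,
            list(
              max_within_discordance = max(sub[grp, grp][upper.tri(sub[grp, grp])]),
              missing_proportions = setNames(
                item$proportion[match(grp, item$variable)], grp
              )
            ),
            sprintf(
              "Variables %s are missing together (discordance < %.2f); they cannot serve each other in imputation models.",
              paste(grp, collapse = ", "), th$block_discordance
            ),
            "review"
          )
        }
      }
    }
  }

  # COLLINEAR_PAIR / PART_WHOLE_REPARAM / RATIO_REDUNDANT from the Spearman matrix
  S <- bundle$multivariate$spearman
  if (!is.null(S)) {
    idx <- which(upper.tri(S$r) & S$r > th$high_corr, arr.ind = TRUE)
    for (k in seq_len(nrow(idx))) {
      v1 <- S$variables[idx[k, 1]]
      v2 <- S$variables[idx[k, 2]]
      rho <- S$r[idx[k, 1], idx[k, 2]]
      comp1 <- dict$component_of[dict$name == v1]
      comp2 <- dict$component_of[dict$name == v2]
      ratio1 <- dict$ratio_of[dict$name == v1]
      ratio2 <- dict$ratio_of[dict$name == v2]
      part_whole <- (!is.na(comp1) && comp1 == v2) || (!is.na(comp2) && comp2 == v1)
      ratio_link <- (!is.na(ratio1) && ratio1 == v2) || (!is.na(ratio2) && ratio2 == v1)
      if (part_whole) {
        whole <- if (!is.na(comp1) && comp1 == v2) v2 else v1
        component <- setdiff(c(v1, v2), whole)
        derived <- derived_variable_def(whole, component, dict)
        add(
          "PART_WHOLE_REPARAM", c(whole, component),
          list(spearman = rho, derived_variable = derived),
          sprintf(
            "Replace %s by %s = %s - %s alongside %s: removes the built-in correlation (Spearman %.2f) while retaining all information.",
            whole, derived$new_name, whole, component, component, rho
          ),
          "reparameterize"
        )
      } else if (ratio_link) {
        add(
          "RATIO_REDUNDANT", c(v1, v2),
          list(spearman = rho),
          sprintf(
            "Derived percentage variable largely collinear with its source (Spearman %.2f between %s and %s); the ratio form may not be needed.",
            rho, v1, v2
          ),
          "review"
        )
      } else {
        add(
          "COLLINEAR_PAIR", c(v1, v2),
          list(spearman = rho),
          sprintf("Review scatterplot of %s and %s (Spearman %.2f > %.2f).", v1, v2, rho, th$high_corr),
          "review"
        )
      }
    }
  }

  # SPARSE_CATEGORY_COLLAPSE
  for (cs in bundle$univariate$categorical) {
    sparse <- cs$levels[cs$levels$count < th$min_level_count, ]
    if (nrow(sparse) > 0L && cs$variable %in% predictor_variables(dict)) {
      add(
        "SPARSE_CATEGORY_COLLAPSE", cs$variable,
        list(levels = setNames(sparse$count, sparse$level)),
        sprintf(
          "Level(s) %s of %s have fewer than %d observations; consider collapsing with a suitable other level.",
          paste(sparse$level, collapse = ", "), cs$variable, th$min_level_count
        ),
        "review"
      )
    }
  }

  out <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble(
      rule_id = character(), variables = list(), evidence = list(),
      action = character(), severity = character()
    )
  }
  # canonical order: by rule then first variable, so evaluation order never matters
  if (nrow(out)) {
    first_var <- vapply(out$variables, `[[`, "", 1L)
    out <- out[order(out$rule_id, first_var), ]
  }
  class(out) <- unique(c("ida_findings", class(out)))
  out
}

# Connected components of an undirected adjacency matrix (logical).
components_of <- function(adj) {
  n <- nrow(adj)
  seen <- rep(FALSE, n)
  comps <- list()
  for (i in seq_len(n)) {
    if (seen[i]) next
    queue <- i
    comp <- integer(0)
    while (length(queue)) {
      j <- queue[1]
      queue <- queue[-1]
      if (seen[j]) next
      seen[j] <- TRUE
      comp <- c(comp, j)
      queue <- c(queue, which(adj[j, ] & !seen))
    }
    comps[[length(comps) + 1L]] <- colnames(adj)[sort(comp)]
  }
  comps
}

#' Define a part-whole difference variable
#'
#' For a whole W and one of its physical components C, defines the new
#' variable `W_NO<C> = W - C` (e.g. the white blood count minus
#' neutrophils), which can replace W in a model to remove the built-in
#' collinearity while keeping coefficients interpretable.
#'
#' @param whole,component Variable names linked by `component_of`.
#' @param dict An `ida_dictionary` containing both.
#' @return List of class `derived_variable_def`: `new_name`, `formula`
#'   (string `whole - component`), `whole`, `component`, `note`.
#' @export
derived_variable_def <- function(whole, component, dict) {
  if (!all(c(whole, component) %in% dict$name)) {
    abort("Both source variables must exist in the dictionary.")
  }
  new_name <- paste0(whole, "_NO", component)
  if (new_name %in% dict$name) {
    abort(sprintf("Derived name %s already used in the dictionary.", new_name))
  }
  structure(
    list(
      new_name = new_name,
      formula = sprintf("%s - %s", whole, component),
      whole = whole, component = component,
      note = sprintf(
        "%s is a physical component of %s; using %s and %s removes their built-in correlation.",
        component, whole, new_name, component
      )
    ),
    class = "derived_variable_def"
  )
}

#' Summarize findings as a structured amendment document
#'
#' Groups the findings by recommended action, lists for each the triggering
#' rule, threshold-backed evidence and affected variables (variables with
#' several findings are merged into one entry citing all rules), and
#' reports the candidate predictor-set delta (how many predictors would
#' remain if all discard candidates were excluded). States explicitly that
#' no outcome association was used.
#'
#' @param findings An `ida_findings` tibble.
#' @param plan An `ida_plan`.
#' @param dict An `ida_dictionary`.
#' @return List of class `ida_amendments`: `by_severity` (named list of
#'   finding tibbles), `merged_by_variable` (tibble `variable`, `rules`),
#'   `n_predictors`, `n_discard_candidates`, `n_remaining`, `statement`,
#'   `markdown` (character vector of lines).
#' @export
amendment_summary <- function(findings, plan, dict) {
  predictors <- predictor_variables(dict)
  discard <- unique(unlist(findings$variables[findings$severity == "discard_candidate"]))
  discard <- intersect(discard, predictors)
  merged <- if (nrow(findings)) {
    tibble(
      variable = unlist(findings$variables),
      rule_id = rep(findings$rule_id, lengths(findings$variables))
    ) |>
      dplyr::distinct() |>
      dplyr::group_by(.data$variable) |>
      dplyr::summarise(rules = paste(sort(unique(.data$rule_id)), collapse = "; "), .groups = "drop")
  } else {
    tibble(variable = character(), rules = character())
  }
  statement <- if (nrow(findings) == 0L) {
    "No amendments triggered: all pre-specified screening rules passed."
  } else {
    sprintf(
      "%d finding(s) from pre-specified rules; %d of %d candidate predictors are discard candidates, leaving %d. No predictor-outcome association was evaluated.",
      nrow(findings), length(discard), length(predictors), length(predictors) - length(discard)
    )
  }
  md <- c(
    "## Candidate amendments to the statistical analysis plan", "",
    statement, ""
  )
  for (sev in c("discard_candidate", "reparameterize", "review")) {
    sub <- findings[findings$severity == sev, ]
    if (nrow(sub) == 0L) next
    md <- c(md, sprintf("### %s", sev), "")
    for (i in seq_len(nrow(sub))) {
      md <- c(md, sprintf(
        "- [%s] %s", sub$rule_id[i], sub$action[i]
      ))
    }
    md <- c(md, "")
  }
  structure(
    list(
      by_severity = split(findings, findings$severity),
      merged_by_variable = merged,
      n_predictors = length(predictors),
      n_discard_candidates = length(discard),
      n_remaining = length(predictors) - length(discard),
      statement = statement,
      markdown = md
    ),
    class = "ida_amendments"
  )
}
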