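#' Unit (participant) missingness summary
#'
#' Passes through externally supplied enrollment counts and computes the
#' attrition fractions between successive stages. When no counts are
#' available (the usual case for registry exports, where only assessed
#' units ever enter the data) the result is an explicit "not evaluable"
#' marker rather than a table.
#'
#' @param eligible,assessed,recruited Optional non-negative counts of
#'   potentially eligible, assessed, and recruited units.
#' @return Either the character marker `"not evaluable"` or a tibble with
#'   one row per enrollment transition and its attrition fraction.
#' @export
unit_missingness_summary <- function(eligible = NULL, assessed = NULL, recruited = NULL) {
  counts <- c(eligible = eligible, assessed = assessed, recruited = recruited)
  if (is.null(counts) || length(counts) == 0L) {
    return(structure("not evaluable", class = "ida_not_evaluable"))
  }
  if (any(counts < 0)) abort("Enrollment counts must be non-negative.")
  if (any(diff(counts) > 0)) {
    abort("Enrollment counts must be non-increasing along eligible >= assessed >= recruited.")
  }
  if (length(counts) == 1L) {
    return(tibble(stage = names(counts), n = unname(counts), attrition = NA_real_))
  }
  tibble(
    stage = names(counts),
    n = unname(counts),
    attrition = c(NA_real_, unname(1 - counts[-1] / counts[-length(counts)]))
  )
}

#' Item missingness per variable
#'
#' Missing-value count and proportion for every screened variable,
#' including the outcome and the structural variables (identifier columns
#' are excluded).
#'
#' @param ds An `ida_dataset`.
#' @param dict An `ida_dictionary`.
#' @return Tibble with columns `variable`, `role`, `n_total`, `n_missing`,
#'   `proportion`.
#' @export
item_missingness <- function(ds, dict) {
  vars <- intersect(screening_variables(dict), names(ds))
  purrr::map_dfr(vars, function(v) {
    tibble(
      variable = v,
      role = dict$role[dict$name == v],
      n_total = nrow(ds),
      n_missing = sum(is.na(ds[[v]])),
      proportion = sum(is.na(ds[[v]])) / nrow(ds)
    )
  })
}

complete_for_set <- function(ds, members, outcome) {
  cols <- unique(c(outcome, members))
  !Reduce(`|`, lapply(cols, function(v) is.na(ds[[v]])))
}

#' Complete-case cascade over candidate model sets
#'
#' For each candidate model set, counts the observations that are complete
#' in the outcome and every set member. A leading row reports completeness
#' of the outcome alone. For nested sets the complete-case count is
#' non-increasing as sets grow.
#'
#' @param ds An `ida_dataset`.
#' @param plan An `ida_plan` whose `model_sets` are validated against the data.
#' @param dict An `ida_dictionary`.
#' @return Tibble with columns `set_name`, `n_variables`, `n_complete`,
#'   `proportion_complete`.
#' @export
complete_case_cascade <- function(ds, plan, dict) {
  outcome <- dict$name[dict$role == "outcome"]
  sets <- c(list(outcome = character(0)), plan$model_sets)
  purrr::imap_dfr(sets, function(members, set_name) {
    if (set_name != "outcome" && length(members) == 0L) {
      abort(sprintf("Model set '%s' is empty.", set_name))
    }
    ok <- complete_for_set(ds, members, outcome)
    tibble(
      set_name = set_name,
      n_variables = length(members),
      n_complete = sum(ok),
      proportion_complete = mean(ok)
    )
  })
}

# Bin a continuous structural variable for stratified displays. Default:
# decades clipped to the observed range.
structural_bins <- function(x, rule = "decades") {
  width <- if (identical(rule, "decades")) 10 else as.numeric(rule)
  lo <- floor(min(x, na.rm = TRUE) / width) * width
  hi <- ceiling(max(x, na.rm = TRUE) / width) * width
  if (hi == lo) hi <- lo + width
  cut(x, breaks = seq(lo, hi, by = width), include.lowest = TRUE, right = FALSE)
}

#' Complete-case cascade within structural strata
#'
#' Repeats [complete_case_cascade()] within every cell defined by crossing
#' the structural variables (continuous ones binned by the plan's
#' stratification rule). Cells with fewer than 10 observations are flagged.
#'
#' @inheritParams complete_case_cascade
#' @return Tibble: one row per stratum x model set, with `stratum`,
#'   `n_rows`, `small_stratum` plus the cascade columns.
#' @export
stratified_complete_cases <- function(ds, plan, dict) {
  struct <- dict$name[dict$role == "structural"]
  strata <- lapply(struct, function(v) {
    spec <- dict[dict$name == v, ]
    if (spec$scale %in% c("continuous", "ordinal")) {
      as.character(structural_bins(ds[[v]], plan$structural_strata))
    } else {
      as.character(ds[[v]])
    }
  })
  stratum <- do.call(paste, c(strata, sep = " / "))
  purrr::map_dfr(split(seq_len(nrow(ds)), stratum), function(idx) {
    sub <- ds[idx, , drop = FALSE]
    out <- complete_case_cascade(sub, plan, dict)
    out$stratum <- stratum[idx[1]]
    out$n_rows <- length(idx)
    out$small_stratum <- length(idx) < 10L
    out
  }) |>
    dplyr::relocate("stratum", "n_rows", "small_stratum")
}

#' Pairwise missingness discordance matrix
#'
#' For every pair of variables, the exact fraction of rows in which their
#' missingness indicators disagree (one missing, the other observed). This
#' is the distance underlying the missingness-pattern dendrogram. It
#' satisfies `|p_i - p_j| <= d(i,j) <= min(1, p_i + p_j)` where `p` are the
#' per-variable missingness proportions.
#'
#' @param ds An `ida_dataset`.
#' @param variables At least two variable names present in the data.
#' @return A symmetric matrix of class `ida_discordance` with attribute
#'   `missing_proportion` (named per-variable proportions).
#' @export
missingness_discordance_matrix <- function(ds, variables) {
  if (length(variables) < 2L) abort("Need at least 2 variables.")
  M <- vapply(variables, function(v) is.na(ds[[v]]), logical(nrow(ds)))
  storage.mode(M) <- "double"
  n <- nrow(M)
  # d(i,j) = P(exactly one of i,j missing) via cross-products of indicators
  co_missing <- crossprod(M)
  p <- diag(co_missing) / n
  d <- (outer(diag(co_missing), diag(co_missing), `+`) - 2 * co_missing) / n
  dimnames(d) <- list(variables, variables)
  structure(d,
    class = c("ida_discordance", "matrix", "array"),
    missing_proportion = setNames(p, variables)
  )
}

#' Cluster variables by missingness discordance
#'
#' Agglomerative hierarchical clustering of the missingness indicators,
#' using the discordance fractions as distances. Leaves carry the
#' per-variable missingness percentage as an annotation; merge heights are
#' discordance fractions.
#'
#' @param d An `ida_discordance` matrix.
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @return An object of class `ida_dendrogram`: a list with the `hclust`
#'   tree, leaf `labels`, `annotated_labels` (with missing percentages) and
#'   the `linkage` used.
#' @export
cluster_missingness <- function(d, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  if (nrow(d) < 2L) abort("Need at least 2 variables to cluster.")
  hc <- hclust(as.dist(d), method = linkage)
  p <- attr(d, "missing_proportion")
  structure(
    list(
      hclust = hc,
      labels = hc$labels,
      annotated_labels = sprintf("%s (%.0f%%)", hc$labels, 100 * p[hc$labels]),
      linkage = linkage
    ),
    class = "ida_dendrogram"
  )
}

#' Serialize a dendrogram as Newick
#'
#' Branch lengths reflect the merge heights (ultrametric tree), so the
#' depth at which two leaves join equals their cluster merge height.
#'
#' @param dend An `ida_dendrogram`.
#' @param file Optional path; when given the tree is written there.
#' @return The Newick string, invisibly when writing to file.
#' @export
dendrogram_newick <- function(dend, file = NULL) {
  phy <- ape::as.phylo(dend$hclust)
  txt <- ape::write.tree(phy)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Merge table of a dendrogram
#'
#' Plain-table view of the agglomeration: one row per merge with its height.
#'
#' @param dend An `ida_dendrogram`.
#' @return Tibble with columns `step`, `height`, `members` (comma-separated
#'   leaf names of the newly formed cluster).
#' @export
dendrogram_merges <- function(dend) {
  hc <- dend$hclust
  members <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    take <- function(i) if (i < 0) hc$labels[-i] else members[[i]]
    members[[k]] <- c(take(hc$merge[k, 1]), take(hc$merge[k, 2]))
  }
  tibble(
    step = seq_along(hc$height),
    height = hc$height,
    members = vapply(members, paste, "", collapse = ",")
  )
}

#' Contrast structural variables between complete and incomplete cases
#'
#' Splits the observations into complete vs incomplete with respect to a
#' model set (outcome included) and contrasts each structural variable
#' between the two groups: standardized mean difference for continuous
#' variables, per-category proportion difference for categorical ones. No
#' hypothesis tests are computed - screening must stay descriptive.
#'
#' @param ds An `ida_dataset`.
#' @param model_set Character vector of predictor names defining
#'   completeness.
#' @param dict An `ida_dictionary`.
#' @return Tibble with columns `variable`, `level` (`NA` for continuous),
#'   `summary_complete`, `summary_incomplete`, `std_difference`
#'   (standardized mean difference, or proportion difference per level).
#'   If either group is empty, a zero-row tibble with attribute
#'   `degenerate = TRUE`.
#' @export
compare_missingness_groups <- function(ds, model_set, dict) {
  outcome <- dict$name[dict$role == "outcome"]
  ok <- complete_for_set(ds, model_set, outcome)
  empty <- tibble(
    variable = character(), level = character(),
    summary_complete = numeric(), summary_incomplete = numeric(),
    std_difference = numeric()
  )
  if (all(ok) || all(!ok)) {
    attr(empty, "degenerate") <- TRUE
    return(empty)
  }
  struct <- dict$name[dict$role == "structural"]
  out <- purrr::map_dfr(struct, function(v) {
    spec <- dict[dict$name == v, ]
    x <- ds[[v]]
    if (spec$scale %in% c("continuous", "ordinal")) {
      m1 <- mean(x[ok], na.rm = TRUE)
      m0 <- mean(x[!ok], na.rm = TRUE)
      s1 <- sd(x[ok], na.rm = TRUE)
      s0 <- sd(x[!ok], na.rm = TRUE)
      pooled <- sqrt((s1^2 + s0^2) / 2)
      tibble(
        variable = v, level = NA_character_,
        summary_complete = m1, summary_incomplete = m0,
        std_difference = if (pooled > 0) (m1 - m0) / pooled else 0
      )
    } else {
      levs <- sort(unique(x[!is.na(x)]))
      purrr::map_dfr(levs, function(l) {
        p1 <- mean(x[ok] == l, na.rm = TRUE)
        p0 <- mean(x[!ok] == l, na.rm = TRUE)
        tibble(
          variable = v, level = as.character(l),
          summary_complete = p1, summary_incomplete = p0,
          std_difference = p1 - p0
        )
      })
    }
  })
  attr(out, "degenerate") <- FALSE
  out
}
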