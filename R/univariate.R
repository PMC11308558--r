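#' Gini mean difference
#'
#' Mean absolute difference between all ordered pairs of observations,
#' `sum_{i != j} |x_i - x_j| / (n (n - 1))`: a dispersion measure more
#' robust to shape than the standard deviation. Computed by the
#' O(n log n) sorted-prefix identity
#' `GMD = 2 / (n (n - 1)) * sum_i (2 i - n - 1) x_(i)`.
#'
#' @param x Numeric vector; missing values are dropped.
#' @return The Gini mean difference (0 for a constant vector).
#' @export
#' @examples
#' gini_mean_difference(c(1, 2, 3)) # 4/3
gini_mean_difference <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2L) abort("Gini mean difference needs at least 2 non-missing values.")
  xs <- sort(x)
  i <- seq_len(n)
  2 * sum((2 * i - n - 1) * xs) / (n * (n - 1))
}

#' Concentration ratio of a sample
#'
#' Modal frequency divided by the average frequency per distinct value,
#' `mode_count / (n / n_distinct)`. Values well above 1 indicate a spike
#' (e.g. a spike at zero in a zero-inflated laboratory measurement); 1 for
#' both all-distinct and constant samples.
#'
#' @param x Vector; missing values are dropped.
#' @return A number `>= 1`.
#' @export
concentration_ratio <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 1L) abort("Need at least one non-missing value.")
  tab <- table(x)
  max(tab) / (length(x) / length(tab))
}

#' Summarize a categorical variable
#'
#' Frequencies and proportions over the observed levels; missing values are
#' excluded from denominators but reported. If a collapse map is supplied
#' (or declared in the dictionary), collapsed-category counts are reported
#' alongside.
#'
#' @param ds An `ida_dataset`.
#' @param var Name of a binary/nominal/ordinal variable.
#' @param dict An `ida_dictionary`.
#' @param collapse_map Optional named character vector mapping original to
#'   collapsed categories; defaults to the dictionary's declaration.
#' @return A list of class `ida_categorical_summary`: `variable`,
#'   `n_nonmissing`, `n_missing`, `levels` (tibble level/count/proportion),
#'   and `collapsed` (tibble, or `NULL` without a map). Levels absent from
#'   the map keep their own name.
#' @export
summarize_categorical <- function(ds, var, dict, collapse_map = NULL) {
  spec <- dict[dict$name == var, ]
  if (nrow(spec) == 0L) abort(sprintf("Variable %s not in dictionary.", var))
  if (!spec$scale %in% c("nominal", "ordinal", "binary")) {
    abort(sprintf("Variable %s is %s; categorical summary needs a categorical scale.", var, spec$scale))
  }
  collapse_map <- collapse_map %||% spec$collapse_map[[1]]
  x <- ds[[var]]
  n_missing <- sum(is.na(x))
  x <- x[!is.na(x)]
  tab <- table(x)
  levels_tbl <- tibble(
    level = names(tab),
    count = as.integer(tab),
    proportion = as.numeric(tab) / max(length(x), 1L)
  )
  collapsed <- NULL
  if (!is.null(collapse_map)) {
    mapped <- ifelse(x %in% names(collapse_map), collapse_map[x], x)
    ctab <- table(mapped)
    collapsed <- tibble(
      level = names(ctab),
      count = as.integer(ctab),
      proportion = as.numeric(ctab) / max(length(x), 1L)
    )
  }
  structure(
    list(
      variable = var, n_nonmissing = length(x), n_missing = n_missing,
      levels = levels_tbl, collapsed = collapsed
    ),
    class = "ida_categorical_summary"
  )
}

#' Summarize a continuous variable
#'
#' The full univariate description used in screening: extremes, the plan's
#' quantiles (linear-interpolation convention, R type 7), mean, standard
#' deviation, interquartile range, Gini mean difference, number of distinct
#' values, the five lowest and five highest values, the mode with its count
#' and proportion, and the concentration ratio.
#'
#' @param ds An `ida_dataset`.
#' @param var Name of a continuous or ordinal variable.
#' @param quantiles Probabilities for the quantile summary.
#' @return A one-row tibble of class `ida_continuous_summary` with
#'   list-columns `quantiles` (named numeric), `five_lowest`,
#'   `five_highest`, `top_values` (tibble of the five most frequent values
#'   with counts).
#' @export
summarize_continuous <- function(ds, var, quantiles = ida_quantile_presets$main) {
  x <- ds[[var]]
  if (is.null(x)) abort(sprintf("Variable %s not in data.", var))
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) abort(sprintf("Variable %s has no non-missing values.", var))
  tab <- table(x)
  vals <- as.numeric(names(tab))
  counts <- as.integer(tab)
  ord <- order(-counts, vals) # ties in frequency broken by value, deterministically
  vals <- vals[ord]
  counts <- counts[ord]
  mode_value <- vals[1]
  n_distinct <- length(vals)
  q <- quantile(x, probs = quantiles, type = 7, names = TRUE)
  iqr <- unname(quantile(x, 0.75, type = 7) - quantile(x, 0.25, type = 7))
  out <- tibble(
    variable = var,
    n_nonmissing = n,
    n_distinct = n_distinct,
    min = min(x),
    max = max(x),
    mean = mean(x),
    sd = if (n > 1) sd(x) else 0,
    iqr = iqr,
    gini_mean_difference = if (n > 1) gini_mean_difference(x) else NA_real_,
    mode_value = mode_value,
    mode_count = counts[1],
    mode_proportion = counts[1] / n,
    concentration_ratio = concentration_ratio(x),
    quantiles = list(q),
    five_lowest = list(head(sort(unique(x)), 5)),
    five_highest = list(tail(sort(unique(x)), 5)),
    top_values = list(tibble(
      value = vals[seq_len(min(5L, n_distinct))],
      count = counts[seq_len(min(5L, n_distinct))]
    ))
  )
  class(out) <- unique(c("ida_continuous_summary", class(out)))
  out
}

#' Detect a spike in a continuous distribution
#'
#' Flags a variable whose modal value concentrates at least the plan's
#' `spike_mode_prop` share of the non-missing observations (boundary
#' included). A spike that no transformation can remove (e.g. a spike at
#' zero) makes a predictor a discard candidate.
#'
#' @param summary An `ida_continuous_summary`.
#' @param plan An `ida_plan` supplying the threshold.
#' @return `NULL` when no spike; otherwise a list of class `ida_spike_flag`
#'   carrying the mode value, its proportion, the concentration ratio and
#'   the five most frequent values with counts.
#' @export
detect_spikes <- function(summary, plan) {
  if (summary$mode_proportion < plan$thresholds$spike_mode_prop) {
    return(NULL)
  }
  structure(
    list(
      variable = summary$variable,
      mode_value = summary$mode_value,
      mode_proportion = summary$mode_proportion,
      concentration_ratio = summary$concentration_ratio,
      top_values = summary$top_values[[1]]
    ),
    class = "ida_spike_flag"
  )
}
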