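#' Pseudo-log transformation
#'
#' `asinh(x / (2 * sigma)) / log(base)`: a log-like transform that is
#' defined for all real values including zero and negatives, antisymmetric,
#' and asymptotically equal to `log_base(x)` for large `x / sigma`. One unit
#' on the transformed scale corresponds approximately to a `base`-fold
#' change in the original value. `sigma` sets the scale below which the
#' transform is approximately linear.
#'
#' @param x Numeric.
#' @param sigma Positive linear-region scale (default 1).
#' @param base Logarithm base greater than 1 (default 10).
#' @return Transformed values, same length as `x`.
#' @export
#' @examples
#' pseudolog(0) # exactly 0
#' pseudolog(1e6) - log10(1e6) # ~ 0
pseudolog <- function(x, sigma = 1, base = 10) {
  if (sigma <= 0) abort("`sigma` must be positive.")
  if (base <= 1) abort("`base` must exceed 1.")
  asinh(x / (2 * sigma)) / log(base)
}

#' Signed cube root
#'
#' `sign(x) * |x|^(1/3)`: a mild symmetrizing transform, monotone and
#' defined on the whole real line.
#'
#' @param x Numeric.
#' @return Transformed values.
#' @export
signed_cube_root <- function(x) {
  sign(x) * abs(x)^(1 / 3)
}

#' Correlation with normal scores
#'
#' Product-moment correlation between the sorted sample and standard-normal
#' quantiles at Blom plotting positions `(i - 3/8) / (n + 1/4)`: a proxy
#' for how close the distribution shape is to Gaussian (1 for exactly
#' normal-looking samples). Location-scale invariant. Used to judge whether
#' a candidate transformation symmetrizes a predictor.
#'
#' @param x Numeric; missing values dropped. Needs at least 3 distinct
#'   values.
#' @return Correlation in (0, 1].
#' @export
normal_scores_correlation <- function(x) {
  x <- x[!is.na(x)]
  if (length(unique(x)) < 3L) {
    abort("Normal-scores correlation needs at least 3 distinct non-missing values.")
  }
  n <- length(x)
  scores <- qnorm((seq_len(n) - 3 / 8) / (n + 1 / 4))
  cor(sort(x), scores)
}

sigma_for <- function(plan, var) {
  s <- plan$pseudolog$sigma_by_variable[[var]]
  if (is.null(s)) plan$pseudolog$sigma else s
}

#' Select symmetrizing transformations for continuous predictors
#'
#' For every continuous predictor, computes the normal-scores correlation
#' of the raw values, the pseudo-log transform and the signed cube root.
#' The pseudo-log is chosen if it improves the correlation by more than
#' the plan's `normdev_gain` threshold (default 0.2 correlation units);
#' otherwise the cube root is chosen if its gain both exceeds the threshold
#' and beats the pseudo-log's; otherwise no transformation. Variables with
#' fewer than 3 distinct values are recorded as not assessable.
#'
#' @param ds An `ida_dataset`.
#' @param dict An `ida_dictionary`.
#' @param plan An `ida_plan` (thresholds, pseudo-log settings).
#' @return Tibble with one row per continuous predictor: `variable`,
#'   `r_raw`, `r_pseudolog`, `r_cuberoot`, `chosen` (`"none"`,
#'   `"pseudolog"`, `"cuberoot"` or `"not assessable"`), `gain`,
#'   `sigma_used`, `base_used`.
#' @export
select_transformations <- function(ds, dict, plan) {
  vars <- intersect(continuous_variables(dict), names(ds))
  thr <- plan$thresholds$normdev_gain
  purrr::map_dfr(vars, function(v) {
    x <- ds[[v]]
    sigma <- sigma_for(plan, v)
    base <- plan$pseudolog$base
    if (length(unique(x[!is.na(x)])) < 3L) {
      return(tibble(
        variable = v, r_raw = NA_real_, r_pseudolog = NA_real_,
        r_cuberoot = NA_real_, chosen = "not assessable", gain = NA_real_,
        sigma_used = sigma, base_used = base
      ))
    }
    r_raw <- normal_scores_correlation(x)
    r_pl <- normal_scores_correlation(pseudolog(x, sigma, base))
    r_cr <- normal_scores_correlation(signed_cube_root(x))
    gain_pl <- r_pl - r_raw
    gain_cr <- r_cr - r_raw
    chosen <- if (gain_pl > thr) {
      "pseudolog"
    } else if (gain_cr > thr && gain_cr > gain_pl) {
      "cuberoot"
    } else {
      "none"
    }
    gain <- switch(chosen,
      pseudolog = gain_pl,
      cuberoot = gain_cr,
      0
    )
    tibble(
      variable = v, r_raw = r_raw, r_pseudolog = r_pl, r_cuberoot = r_cr,
      chosen = chosen, gain = gain, sigma_used = sigma, base_used = base
    )
  })
}

#' Apply chosen transformations to a dataset
#'
#' Materializes the transformed columns selected by
#' [select_transformations()], named with a `t_` prefix (e.g. `t_WBC` for a
#' pseudo-logged white blood count). Untransformed variables are not
#' duplicated.
#'
#' @param ds An `ida_dataset`.
#' @param decisions Output of [select_transformations()].
#' @return The dataset with transformed columns appended.
#' @export
apply_transformations <- function(ds, decisions) {
  chosen <- decisions[decisions$chosen %in% c("pseudolog", "cuberoot"), ]
  for (i in seq_len(nrow(chosen))) {
    v <- chosen$variable[i]
    ds[[paste0("t_", v)]] <- if (chosen$chosen[i] == "pseudolog") {
      pseudolog(ds[[v]], chosen$sigma_used[i], chosen$base_used[i])
    } else {
      signed_cube_root(ds[[v]])
    }
  }
  ds
}

# Column to use for scatter-type displays: the transformed version when one
# was selected, the raw values otherwise.
display_values <- function(ds, var, decisions = NULL) {
  if (!is.null(decisions)) {
    row <- decisions[decisions$variable == var, ]
    if (nrow(row) == 1L && row$chosen == "pseudolog") {
      return(pseudolog(ds[[var]], row$sigma_used, row$base_used))
    }
    if (nrow(row) == 1L && row$chosen == "cuberoot") {
      return(signed_cube_root(ds[[var]]))
    }
  }
  ds[[var]]
}
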