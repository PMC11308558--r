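# Restricted cubic spline basis (truncated-power parameterization,
# normalized by the squared knot span). Returns the nonlinear columns only;
# the linear term is added by the caller. Linear beyond the boundary knots.
rcs_basis <- function(x, knots) {
  k <- length(knots)
  if (k < 3L) {
    return(matrix(numeric(0), nrow = length(x), ncol = 0))
  }
  tk <- knots[k]
  tk1 <- knots[k - 1]
  norm <- (knots[k] - knots[1])^2
  pos3 <- function(u) pmax(u, 0)^3
  out <- vapply(seq_len(k - 2L), function(j) {
    tj <- knots[j]
    (pos3(x - tj) -
      pos3(x - tk1) * (tk - tj) / (tk - tk1) +
      pos3(x - tk) * (tk1 - tj) / (tk - tk1)) / norm
  }, numeric(length(x)))
  matrix(out, nrow = length(x))
}

# Knot locations at equally spaced quantiles: boundary 5%/95% for 4 knots,
# 10%/90% for 3 knots.
rcs_knots <- function(x, n_knots) {
  probs <- if (n_knots >= 4L) {
    seq(0.05, 0.95, length.out = n_knots)
  } else {
    seq(0.10, 0.90, length.out = n_knots)
  }
  unique(quantile(x, probs, type = 7, names = FALSE))
}

# Expanded design for one predictor under the chosen basis. Categorical
# variables become indicator sets regardless of basis; continuous ones get
# a restricted-cubic-spline expansion in the additive basis (4 knots for
# key predictors, 3 otherwise).
predictor_columns <- function(ds, v, dict, basis) {
  spec <- dict[dict$name == v, ]
  x <- ds[[v]]
  if (!spec$scale %in% c("continuous", "ordinal") || !is.numeric(x)) {
    xn <- screening_numeric(x, spec)
    lev <- sort(unique(xn[!is.na(xn)]))
    if (length(lev) <= 2L) {
      return(matrix(xn, ncol = 1, dimnames = list(NULL, v)))
    }
    cols <- vapply(lev[-1], function(l) as.numeric(xn == l), numeric(length(xn)))
    colnames(cols) <- paste0(v, "=", lev[-1])
    return(cols)
  }
  if (basis == "linear") {
    return(matrix(x, ncol = 1, dimnames = list(NULL, v)))
  }
  n_knots <- if (spec$role == "key") 4L else 3L
  knots <- rcs_knots(x[!is.na(x)], n_knots)
  nl <- if (length(knots) >= 3L) rcs_basis(x, knots) else matrix(numeric(0), length(x), 0)
  cols <- cbind(x, nl)
  colnames(cols) <- c(v, if (ncol(nl)) paste0(v, "'", seq_len(ncol(nl))))
  cols
}

safe_det <- function(m) {
  if (length(m) == 0L) {
    return(1)
  }
  det(as.matrix(m))
}

#' Variance inflation factors for a candidate model set
#'
#' Collinearity diagnostics among the predictors of a candidate model,
#' computed on the complete cases of the set; the outcome is never
#' involved. In the `linear` basis the VIF of predictor j is the j-th
#' diagonal element of the inverse correlation matrix of the predictors.
#' In the `additive` basis each continuous predictor is expanded in a
#' restricted cubic spline (4 knots for key predictors, 3 otherwise, knots
#' at equally spaced quantiles) and a generalized VIF per predictor is
#' computed by the determinant formula, reported both raw and scaled to
#' `GVIF^(1/(2 df))` squared for comparability across basis dimensions.
#' A (near-)singular correlation matrix yields an "infinite" marker per
#' affected variable instead of an exception.
#'
#' @param ds An `ida_dataset`.
#' @param model_set Character vector of predictor names.
#' @param dict An `ida_dictionary`.
#' @param plan An `ida_plan`.
#' @param basis `"linear"` (default) or `"additive"`.
#' @return A list of class `ida_vif`: `model_set`, `basis`, `n_complete`
#'   and `table` (tibble `variable`, `df`, `vif` = GVIF, `vif_scaled` =
#'   `(GVIF^(1/(2 df)))^2` which equals the plain VIF when `df = 1`,
#'   `infinite`).
#' @export
vif <- function(ds, model_set, dict, plan, basis = c("linear", "additive")) {
  basis <- match.arg(basis)
  cc <- complete.cases(ds[, model_set, drop = FALSE])
  n_complete <- sum(cc)
  if (n_complete < length(model_set) + 2L) {
    abort("Too few complete cases for the candidate set.")
  }
  sub <- ds[cc, , drop = FALSE]
  blocks <- lapply(model_set, function(v) predictor_columns(sub, v, dict, basis))
  names(blocks) <- model_set
  constant <- vapply(blocks, function(b) any(apply(b, 2, sd) == 0), logical(1))
  X <- do.call(cbind, blocks[!constant])
  R <- cor(X)
  eig <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  near_singular <- min(eig) <= max(eig) / 1e12
  group <- rep(names(blocks)[!constant], vapply(blocks[!constant], ncol, 1L))
  tab <- purrr::map_dfr(model_set, function(v) {
    if (constant[[v]]) {
      return(tibble(variable = v, df = 0L, vif = NA_real_, vif_scaled = NA_real_, infinite = FALSE))
    }
    j <- which(group == v)
    df <- length(j)
    g <- tryCatch(
      safe_det(R[j, j, drop = FALSE]) * safe_det(R[-j, -j, drop = FALSE]) / det(R),
      error = function(e) Inf
    )
    if (!is.finite(g) || g < 0 || near_singular && g > 1e6) g <- Inf
    scaled <- if (is.finite(g)) g^(1 / df) else Inf
    tibble(
      variable = v, df = df, vif = g, vif_scaled = scaled,
      infinite = !is.finite(g) || g >= 1e6
    )
  })
  structure(
    list(
      model_set = model_set, basis = basis, n_complete = n_complete,
      table = tab
    ),
    class = "ida_vif"
  )
}

#' Redundancy analysis of a candidate model set
#'
#' Iteratively fits each remaining predictor on all the others with the
#' additive (restricted cubic spline) basis and records the R-squared; if
#' the maximum exceeds the plan's `redundancy_r2` threshold (default 0.9)
#' that predictor is declared redundant, removed, and the procedure
#' repeats. Categorical predictors enter as indicator sets; a fit that
#' fails is skipped with a notice.
#'
#' @inheritParams vif
#' @return A list of class `ida_redundancy`: `model_set`, `n_complete`,
#'   `r_squared` (first-round R-squared per variable), `removal_sequence`
#'   (tibble `variable`, `r_squared`), `skipped`.
#' @export
redundancy_analysis <- function(ds, model_set, dict, plan) {
  cc <- complete.cases(ds[, model_set, drop = FALSE])
  if (sum(cc) < length(model_set) + 2L) {
    abort("Too few complete cases for the candidate set.")
  }
  sub <- ds[cc, , drop = FALSE]
  # the additive fits need real degrees of freedom, otherwise every
  # predictor looks perfectly predictable from the rest
  p_expanded <- sum(vapply(
    model_set,
    function(v) ncol(predictor_columns(sub, v, dict, "additive")), 1L
  ))
  if (sum(cc) < 3L * p_expanded) {
    abort(sprintf(
      "Too few complete cases (%d) for the additive basis (%d columns); redundancy not assessable.",
      sum(cc), p_expanded
    ))
  }
  threshold <- plan$thresholds$redundancy_r2
  remaining <- model_set
  removal <- list()
  skipped <- character()
  first_round <- NULL
  repeat {
    r2 <- vapply(remaining, function(v) {
      others <- setdiff(remaining, v)
      if (length(others) == 0L) {
        return(NA_real_)
      }
      y <- screening_numeric(sub[[v]], dict[dict$name == v, ])
      X <- do.call(cbind, lapply(others, function(o) predictor_columns(sub, o, dict, "additive")))
      keep <- apply(X, 2, sd) > 0
      if (!any(keep) || sd(y) == 0) {
        return(NA_real_)
      }
      fit <- tryCatch(lm(y ~ X[, keep, drop = FALSE]), error = function(e) NULL)
      if (is.null(fit)) {
        skipped <<- union(skipped, v)
        return(NA_real_)
      }
      # a perfect fit is a legitimate outcome here (exact redundancy)
      suppressWarnings(summary(fit)$r.squared)
    }, numeric(1))
    if (is.null(first_round)) {
      first_round <- setNames(r2, remaining)
    }
    if (all(is.na(r2)) || max(r2, na.rm = TRUE) <= threshold || length(remaining) <= 2L) {
      break
    }
    worst <- remaining[which.max(r2)]
    removal[[length(removal) + 1L]] <- tibble(variable = worst, r_squared = max(r2, na.rm = TRUE))
    remaining <- setdiff(remaining, worst)
  }
  structure(
    list(
      model_set = model_set, n_complete = sum(cc),
      r_squared = first_round,
      removal_sequence = if (length(removal)) dplyr::bind_rows(removal) else tibble(variable = character(), r_squared = numeric()),
      skipped = skipped
    ),
    class = "ida_redundancy"
  )
}
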