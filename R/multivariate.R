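#' Pairwise-complete correlation matrix
#'
#' Spearman (average ranks for ties) or Pearson correlations over all
#' pairwise-complete observations, together with the pairwise sample sizes.
#' Entries based on fewer than `min_pairs` complete pairs are flagged
#' unreliable; pairs with fewer than 2 complete rows are undefined (`NA`).
#' Binary variables enter as 0/1 numerics.
#'
#' @param ds An `ida_dataset`.
#' @param variables At least two variable names.
#' @param dict An `ida_dictionary` (used to code categorical variables
#'   numerically).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param min_pairs Reliability threshold on pairwise-complete counts.
#' @return A list of class `ida_cormat`: `variables`, `method`, `r`
#'   (correlation matrix), `n_pairs` (pairwise-complete counts),
#'   `unreliable` (logical matrix).
#' @export
correlation_matrix <- function(ds, variables, dict, method = c("spearman", "pearson"),
                               min_pairs = 30L) {
  method <- match.arg(method)
  if (length(variables) < 2L) abort("Need at least 2 variables.")
  X <- vapply(
    variables,
    function(v) screening_numeric(ds[[v]], dict[dict$name == v, ]),
    numeric(nrow(ds))
  )
  r <- suppressWarnings(cor(X, use = "pairwise.complete.obs", method = method))
  n_pairs <- crossprod(!is.na(X))
  undefined <- n_pairs < 2L
  r[undefined] <- NA_real_
  structure(
    list(
      variables = variables, method = method, r = r,
      n_pairs = n_pairs, unreliable = n_pairs < min_pairs
    ),
    class = "ida_cormat"
  )
}

#' @rdname correlation_matrix
#' @export
spearman_matrix <- function(ds, variables, dict, min_pairs = 30L) {
  correlation_matrix(ds, variables, dict, method = "spearman", min_pairs = min_pairs)
}

#' @rdname correlation_matrix
#' @export
pearson_matrix <- function(ds, variables, dict, min_pairs = 30L) {
  correlation_matrix(ds, variables, dict, method = "pearson", min_pairs = min_pairs)
}

#' Long-format view of a correlation matrix
#'
#' @param m An `ida_cormat`.
#' @return Tibble with columns `var1`, `var2`, `method`, `r`, `n_pairs`,
#'   `unreliable`; one row per unordered pair (upper triangle).
#' @export
correlation_long <- function(m) {
  idx <- which(upper.tri(m$r), arr.ind = TRUE)
  tibble(
    var1 = m$variables[idx[, 1]],
    var2 = m$variables[idx[, 2]],
    method = m$method,
    r = m$r[idx],
    n_pairs = as.integer(m$n_pairs[idx]),
    unreliable = m$unreliable[idx]
  )
}

#' Pairs where rank and product-moment correlation disagree
#'
#' Lists predictor pairs whose Spearman and Pearson coefficients differ by
#' more than `delta` correlation units, sorted by discrepancy. Such
#' disagreement typically signals influential points or nonlinearity and
#' the pair's scatterplot (on the chosen transformed scales) should be
#' reviewed.
#'
#' @param S,P `ida_cormat` objects (Spearman and Pearson) on identical
#'   variable sets.
#' @param delta Discrepancy threshold (default 0.1).
#' @return Tibble `var1`, `var2`, `spearman`, `pearson`, `discrepancy`,
#'   plus attribute `n_pairs_total` (number of pairs compared).
#' @export
correlation_discrepancies <- function(S, P, delta = 0.1) {
  if (!identical(S$variables, P$variables)) {
    abort("Spearman and Pearson matrices must cover identical variables.")
  }
  idx <- which(upper.tri(S$r), arr.ind = TRUE)
  disc <- abs(S$r[idx] - P$r[idx])
  keep <- !is.na(disc) & disc > delta
  out <- tibble(
    var1 = S$variables[idx[, 1]][keep],
    var2 = S$variables[idx[, 2]][keep],
    spearman = S$r[idx][keep],
    pearson = P$r[idx][keep],
    discrepancy = disc[keep]
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$discrepancy))
  attr(out, "n_pairs_total") <- nrow(idx)
  out
}

#' Associations of predictors with the structural variables
#'
#' For each continuous structural variable (e.g. age): the Spearman
#' correlation of every predictor with it, within each stratum of the
#' categorical structural variables (e.g. separately for males and
#' females). For categorical structural variables alone: per-level medians
#' of each predictor. Strata with fewer than `min_pairs` complete pairs are
#' flagged.
#'
#' @param ds An `ida_dataset`.
#' @param dict An `ida_dictionary`.
#' @param plan An `ida_plan`.
#' @return Tibble `predictor`, `structural`, `stratum`, `spearman`,
#'   `n_pairs`, `unreliable`.
#' @export
structural_association_table <- function(ds, dict, plan) {
  struct <- dict$name[dict$role == "structural"]
  struct_cont <- struct[dict$scale[match(struct, dict$name)] %in% c("continuous", "ordinal")]
  struct_cat <- setdiff(struct, struct_cont)
  predictors <- setdiff(intersect(continuous_variables(dict), names(ds)), struct)
  strata <- if (length(struct_cat)) {
    interaction(lapply(struct_cat, function(v) ds[[v]]), sep = "/", drop = TRUE)
  } else {
    factor(rep("all", nrow(ds)))
  }
  purrr::map_dfr(struct_cont, function(sv) {
    purrr::map_dfr(predictors, function(p) {
      purrr::map_dfr(levels(strata), function(g) {
        rows <- which(strata == g)
        ok <- rows[!is.na(ds[[sv]][rows]) & !is.na(ds[[p]][rows])]
        rho <- if (length(ok) >= 2L) {
          suppressWarnings(cor(ds[[sv]][ok], ds[[p]][ok], method = "spearman"))
        } else {
          NA_real_
        }
        tibble(
          predictor = p, structural = sv, stratum = g,
          spearman = rho, n_pairs = length(ok),
          unreliable = length(ok) < plan$min_pairs
        )
      })
    })
  })
}

#' Joint-distribution screen for declared interaction pairs
#'
#' For every predictor pair declared in the plan's interactions: the
#' Spearman correlation and a sparsity grid - counts over the cross-tab of
#' the two variables' quartile bins. Strong association between interaction
#' partners signals that the interaction would be estimated imprecisely.
#'
#' @param ds An `ida_dataset`.
#' @param plan An `ida_plan` with declared `interactions`.
#' @param dict An `ida_dictionary`.
#' @param decisions Optional transformation decisions; scatter data use the
#'   chosen transformed scale.
#' @return A list, one element per pair, each with `pair`, `spearman`,
#'   `n_complete`, `grid` (4 x 4 count matrix) and `scatter` (tibble of the
#'   display values). Empty list when no interactions are declared.
#' @export
interaction_screen <- function(ds, plan, dict, decisions = NULL) {
  purrr::map(plan$interactions, function(pair) {
    x <- screening_numeric(ds[[pair[1]]], dict[dict$name == pair[1], ])
    y <- screening_numeric(ds[[pair[2]]], dict[dict$name == pair[2], ])
    ok <- !is.na(x) & !is.na(y)
    qx <- quantile(x[ok], c(0.25, 0.5, 0.75), type = 7)
    qy <- quantile(y[ok], c(0.25, 0.5, 0.75), type = 7)
    bx <- cut(x[ok], breaks = unique(c(-Inf, qx, Inf)), labels = FALSE)
    by <- cut(y[ok], breaks = unique(c(-Inf, qy, Inf)), labels = FALSE)
    list(
      pair = pair,
      spearman = suppressWarnings(cor(x[ok], y[ok], method = "spearman")),
      n_complete = sum(ok),
      grid = unclass(table(bx, by)),
      scatter = tibble(
        x = display_values(ds, pair[1], decisions)[ok],
        y = display_values(ds, pair[2], decisions)[ok]
      )
    )
  })
}

#' Variable clustering on squared rank correlation
#'
#' Agglomerative clustering of predictors with similarity `rho_S^2`
#' (squared Spearman correlation, so strong negative association also
#' clusters) and distance `1 - rho_S^2`, average linkage. Pairs whose
#' Spearman correlation exceeds `high_corr` are listed for scatterplot
#' review. Variables with undefined correlation entries are excluded with a
#' notice.
#'
#' @param S An `ida_cormat` (Spearman).
#' @param plan An `ida_plan` (`thresholds$high_corr`).
#' @return A list of class `ida_varclust`: `dendrogram`
#'   (`ida_dendrogram`), `high_corr_pairs` (tibble `var1`, `var2`, `spearman`),
#'   `excluded` (character).
#' @export
variable_clusters <- function(S, plan) {
  r <- S$r
  bad <- colnames(r)[colSums(is.na(r)) > 0]
  keep <- setdiff(colnames(r), bad)
  if (length(keep) < 2L) abort("Fewer than 2 variables with defined correlations.")
  r2 <- r[keep, keep]^2
  d <- 1 - r2
  hc <- hclust(as.dist(d), method = "average")
  dend <- structure(
    list(
      hclust = hc, labels = hc$labels,
      annotated_labels = hc$labels, linkage = "average"
    ),
    class = "ida_dendrogram"
  )
  idx <- which(upper.tri(r) & r > plan$thresholds$high_corr, arr.ind = TRUE)
  pairs <- tibble(
    var1 = S$variables[idx[, 1]],
    var2 = S$variables[idx[, 2]],
    spearman = r[idx]
  )
  structure(
    list(dendrogram = dend, high_corr_pairs = pairs, excluded = bad),
    class = "ida_varclust"
  )
}
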