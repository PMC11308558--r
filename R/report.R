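# --- serialization ---------------------------------------------------------

tidy_quantiles <- function(q) as.list(setNames(as.numeric(q), names(q)))

continuous_flat <- function(continuous) {
  if (is.null(continuous) || nrow(continuous) == 0L) {
    return(list())
  }
  lapply(seq_len(nrow(continuous)), function(i) {
    row <- continuous[i, ]
    list(
      variable = row$variable, n_nonmissing = row$n_nonmissing,
      n_distinct = row$n_distinct, min = row$min, max = row$max,
      mean = row$mean, sd = row$sd, iqr = row$iqr,
      gini_mean_difference = row$gini_mean_difference,
      mode_value = row$mode_value, mode_count = row$mode_count,
      mode_proportion = row$mode_proportion,
      concentration_ratio = row$concentration_ratio,
      quantiles = tidy_quantiles(row$quantiles[[1]]),
      five_lowest = as.numeric(row$five_lowest[[1]]),
      five_highest = as.numeric(row$five_highest[[1]]),
      top_values = as.data.frame(row$top_values[[1]])
    )
  })
}

cormat_flat <- function(m) {
  if (is.null(m)) {
    return(NULL)
  }
  list(
    variables = m$variables, method = m$method,
    r = unname(m$r), n_pairs = unname(m$n_pairs)
  )
}

vif_flat <- function(v) {
  if (is.null(v) || is.character(v)) {
    return(list(error = if (is.character(v)) v else "not computed"))
  }
  list(basis = v$basis, n_complete = v$n_complete, table = as.data.frame(v$table))
}

#' Serialize a screening bundle to plain lists
#'
#' Loss-free (full numeric precision) representation of the bundle used
#' for the machine-readable results file. Timestamps are excluded so that
#' identical inputs and seed yield byte-identical serializations.
#'
#' @param bundle An `ida_bundle`.
#' @return A nested list of plain types.
#' @export
bundle_to_list <- function(bundle) {
  miss <- bundle$missingness
  mv <- bundle$multivariate
  list(
    provenance = list(
      n_rows = bundle$provenance$n_rows,
      n_variables = bundle$provenance$n_variables,
      n_predictors = bundle$provenance$n_predictors,
      seed = bundle$provenance$seed,
      blinded = bundle$provenance$blinded,
      blinding_checksum = if (!is.null(bundle$provenance$blinding)) {
        bundle$provenance$blinding$permutation_checksum
      },
      thresholds = bundle$provenance$plan$thresholds,
      quantiles = bundle$provenance$plan$quantiles
    ),
    validation = as.data.frame(bundle$validation),
    missingness = list(
      unit = if (inherits(miss$unit, "ida_not_evaluable")) "not evaluable" else as.data.frame(miss$unit),
      item = as.data.frame(miss$item),
      cascade = as.data.frame(miss$cascade),
      stratified = as.data.frame(miss$stratified),
      discordance = if (!is.null(miss$discordance)) {
        list(
          variables = colnames(miss$discordance),
          d = unname(unclass(miss$discordance)),
          missing_proportion = as.numeric(attr(miss$discordance, "missing_proportion"))
        )
      },
      dendrogram_newick = if (!is.null(miss$dendrogram)) dendrogram_newick(miss$dendrogram),
      dendrogram_merges = if (!is.null(miss$dendrogram)) as.data.frame(dendrogram_merges(miss$dendrogram)),
      group_contrasts = if (isTRUE(attr(miss$group_contrasts, "degenerate"))) {
        "degenerate split"
      } else {
        as.data.frame(miss$group_contrasts)
      }
    ),
    univariate = list(
      categorical = lapply(bundle$univariate$categorical, function(cs) {
        list(
          variable = cs$variable, n_nonmissing = cs$n_nonmissing,
          n_missing = cs$n_missing, levels = as.data.frame(cs$levels),
          collapsed = if (!is.null(cs$collapsed)) as.data.frame(cs$collapsed)
        )
      }),
      continuous = continuous_flat(bundle$univariate$continuous),
      spikes = lapply(bundle$univariate$spikes, function(s) {
        list(
          variable = s$variable, mode_value = s$mode_value,
          mode_proportion = s$mode_proportion,
          concentration_ratio = s$concentration_ratio,
          top_values = as.data.frame(s$top_values)
        )
      })
    ),
    transforms = as.data.frame(bundle$transforms),
    multivariate = list(
      spearman = cormat_flat(mv$spearman),
      pearson = cormat_flat(mv$pearson),
      discrepancies = if (!is.null(mv$discrepancies)) as.data.frame(mv$discrepancies),
      n_pairs_compared = attr(mv$discrepancies, "n_pairs_total"),
      structural = as.data.frame(mv$structural),
      interactions = lapply(mv$interactions, function(it) {
        list(
          pair = it$pair, spearman = it$spearman,
          n_complete = it$n_complete, grid = unname(it$grid)
        )
      }),
      clusters = if (!is.null(mv$clusters)) {
        list(
          newick = dendrogram_newick(mv$clusters$dendrogram),
          high_corr_pairs = as.data.frame(mv$clusters$high_corr_pairs),
          excluded = mv$clusters$excluded
        )
      },
      vif = lapply(mv$vif, function(v) {
        list(
          set_name = v$set_name,
          linear = vif_flat(v$linear),
          additive = vif_flat(v$additive)
        )
      }),
      redundancy = lapply(mv$redundancy, function(r) {
        if (is.character(r)) {
          return(list(error = r))
        }
        list(
          n_complete = r$n_complete,
          r_squared = as.list(r$r_squared),
          removal_sequence = as.data.frame(r$removal_sequence),
          skipped = r$skipped
        )
      })
    ),
    findings = lapply(seq_len(nrow(bundle$findings)), function(i) {
      ev <- bundle$findings$evidence[[i]]
      ev <- lapply(ev, function(e) if (inherits(e, "derived_variable_def")) unclass(e) else e)
      list(
        rule_id = bundle$findings$rule_id[i],
        variables = bundle$findings$variables[[i]],
        evidence = ev,
        action = bundle$findings$action[i],
        severity = bundle$findings$severity[i]
      )
    }),
    amendments = list(
      statement = bundle$amendments$statement,
      n_predictors = bundle$amendments$n_predictors,
      n_discard_candidates = bundle$amendments$n_discard_candidates,
      n_remaining = bundle$amendments$n_remaining
    ),
    checklist = as.data.frame(bundle$checklist)
  )
}

signif_fmt <- function(x) {
  ifelse(is.na(suppressWarnings(as.numeric(x))), as.character(x),
    formatC(signif(as.numeric(x), 3), format = "g", digits = 3)
  )
}

md_table <- function(df, max_rows = 50L) {
  if (nrow(df) == 0L) {
    return("(empty)")
  }
  df <- utils::head(df, max_rows)
  cells <- vapply(df, function(col) {
    if (is.numeric(col)) signif_fmt(col) else as.character(col)
  }, character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  c(
    paste0("| ", paste(names(df), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
    apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  )
}

# --- rendering -------------------------------------------------------------

#' Render a screening bundle
#'
#' Renders the bundle as a human-readable report (markdown or a minimal
#' HTML wrapping of it; displayed values rounded to 3 significant digits)
#' or as the loss-free machine-readable JSON. Sections follow the
#' checklist order (prerequisites, missing values, univariate,
#' multivariate, consequences) and each is tagged with its checklist item
#' id so a report can be audited for coverage. With `plots = TRUE` (and
#' ggplot2 available) combo plots and dendrogram images are written next
#' to the report and referenced from it.
#'
#' @param bundle An `ida_bundle`.
#' @param format `"markdown"`, `"html"` or `"json"`.
#' @param plots Emit plot files (markdown/html only).
#' @param plot_dir Directory for plot files (default: a `figures`
#'   subdirectory of the working directory).
#' @return A character scalar: the rendered document.
#' @export
render_report <- function(bundle, format = c("markdown", "html", "json"),
                          plots = FALSE, plot_dir = "figures") {
  if (length(format) == 1L && !format %in% c("markdown", "html", "json")) {
    abort(sprintf("Unknown report format '%s'.", format))
  }
  format <- match.arg(format)
  if (format == "json") {
    return(as.character(jsonlite::toJSON(
      bundle_to_list(bundle),
      auto_unbox = TRUE, digits = NA, na = "null", null = "null", pretty = TRUE
    )))
  }
  md <- render_markdown(bundle, plots = plots, plot_dir = plot_dir)
  if (format == "markdown") {
    return(paste(md, collapse = "\n"))
  }
  paste(c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>IDA report</title></head><body><pre>",
    md, "</pre></body></html>"
  ), collapse = "\n")
}

render_markdown <- function(bundle, plots = FALSE, plot_dir = "figures") {
  miss <- bundle$missingness
  mv <- bundle$multivariate
  plot_refs <- character()
  if (plots) {
    plot_refs <- emit_plots(bundle, plot_dir)
  }
  lines <- c(
    "# Initial data analysis report",
    "",
    sprintf(
      "Screened %d observations on %d variables (%d predictors). Outcome %s.",
      bundle$provenance$n_rows, bundle$provenance$n_variables,
      bundle$provenance$n_predictors,
      if (bundle$provenance$blinded) "blinded by seeded permutation" else "NOT blinded"
    ),
    if (!is.null(bundle$provenance$blinding)) {
      sprintf(
        "Blinding: seed %d, permutation checksum %s, at %s.",
        bundle$provenance$blinding$seed,
        bundle$provenance$blinding$permutation_checksum,
        bundle$provenance$blinding$timestamp
      )
    },
    "",
    "## Prerequisites",
    "",
    "### [PRE1] Research aim",
    "Documented in the statistical analysis plan; not a computation.",
    "",
    "### [PRE2] Analysis strategy / plan validation",
    md_table(as.data.frame(bundle$validation)),
    "",
    "### [PRE3] Data dictionary",
    "Dictionary loaded and validated against the data.",
    "",
    "### [PRE4] Domain expertise",
    "Variable roles, part-whole and ratio relations taken from the dictionary.",
    "",
    "## Missing values",
    "",
    "### [M1] Participant (unit) missingness",
    if (inherits(miss$unit, "ida_not_evaluable")) "not evaluable" else md_table(as.data.frame(miss$unit)),
    "",
    "### [M2] Item missingness",
    md_table(dplyr::arrange(as.data.frame(miss$item), dplyr::desc(.data$proportion)), max_rows = 60L),
    "",
    "### [M3] Complete cases",
    md_table(as.data.frame(miss$cascade)),
    "",
    "### [M4] Missingness patterns",
    md_table(as.data.frame(miss$stratified), max_rows = 80L),
    "",
    if (!is.null(miss$dendrogram)) {
      c(
        "Missingness dendrogram (Newick, merge heights = discordance):",
        "```", dendrogram_newick(miss$dendrogram), "```"
      )
    } else {
      "Fewer than two predictors with missing values; no dendrogram."
    },
    "",
    "### [ME1] Predictors of missingness",
    if (isTRUE(attr(miss$group_contrasts, "degenerate"))) {
      "degenerate split (no or only incomplete cases)"
    } else {
      md_table(as.data.frame(miss$group_contrasts))
    },
    "",
    "## Univariate descriptions",
    "",
    "### [U1] Categorical variables",
    unlist(lapply(bundle$univariate$categorical, function(cs) {
      c(
        sprintf("**%s** (missing: %d)", cs$variable, cs$n_missing),
        md_table(as.data.frame(cs$levels)), ""
      )
    })),
    "### [U2] Continuous variables",
    md_table(
      dplyr::select(
        as.data.frame(bundle$univariate$continuous),
        -dplyr::any_of(c("quantiles", "five_lowest", "five_highest", "top_values"))
      ),
      max_rows = 60L
    ),
    "",
    "Transformation assessment (normal-scores correlation):",
    md_table(as.data.frame(bundle$transforms), max_rows = 60L),
    "",
    sprintf(
      "Spike flags: %s",
      if (length(bundle$univariate$spikes)) paste(names(bundle$univariate$spikes), collapse = ", ") else "none"
    ),
    "",
    "### [UE1] Extreme values",
    md_table(tibble(
      variable = bundle$univariate$continuous$variable,
      five_lowest = vapply(bundle$univariate$continuous$five_lowest, function(v) paste(signif_fmt(v), collapse = ", "), ""),
      five_highest = vapply(bundle$univariate$continuous$five_highest, function(v) paste(signif_fmt(v), collapse = ", "), "")
    ), max_rows = 60L),
    "",
    "## Multivariate descriptions",
    "",
    "### [V1] Associations with structural variables",
    md_table(as.data.frame(mv$structural), max_rows = 100L),
    "",
    "### [V2] Spearman correlation matrix",
    if (!is.null(mv$spearman)) {
      sprintf(
        "%d variables; %d pairwise entries flagged unreliable (fewer than %d complete pairs).",
        length(mv$spearman$variables), sum(mv$spearman$unreliable[upper.tri(mv$spearman$unreliable)]),
        bundle$provenance$plan$min_pairs
      )
    } else {
      "not evaluable"
    },
    "",
    "### [V3] Interactions",
    if (length(mv$interactions)) {
      unlist(lapply(mv$interactions, function(it) {
        sprintf(
          "- %s x %s: Spearman %s over %d complete pairs",
          it$pair[1], it$pair[2], signif_fmt(it$spearman), it$n_complete
        )
      }))
    } else {
      "No interactions declared."
    },
    "",
    "### [VE1] Spearman vs Pearson discrepancies",
    if (!is.null(mv$discrepancies)) {
      c(
        sprintf(
          "%d of %d pairs differ by more than %s correlation units.",
          nrow(mv$discrepancies), attr(mv$discrepancies, "n_pairs_total"),
          signif_fmt(bundle$provenance$plan$thresholds$spearman_pearson_delta)
        ),
        md_table(as.data.frame(mv$discrepancies), max_rows = 40L)
      )
    } else {
      "not evaluable"
    },
    "",
    "### [VE2] Variable clustering",
    if (!is.null(mv$clusters)) {
      c(
        "High-correlation pairs (Spearman above threshold):",
        md_table(as.data.frame(mv$clusters$high_corr_pairs)),
        "```", dendrogram_newick(mv$clusters$dendrogram), "```"
      )
    } else {
      "not evaluable"
    },
    "",
    "### [VE3] Variance inflation and redundancy",
    unlist(lapply(mv$vif, function(v) {
      c(
        sprintf("**Model set: %s**", v$set_name),
        if (!is.character(v$linear)) c("Linear basis:", md_table(as.data.frame(v$linear$table))) else sprintf("Linear basis: %s", v$linear),
        if (!is.character(v$additive)) c("Additive basis (GVIF):", md_table(as.data.frame(v$additive$table))) else sprintf("Additive basis: %s", v$additive),
        ""
      )
    })),
    unlist(lapply(names(mv$redundancy), function(nm) {
      r <- mv$redundancy[[nm]]
      if (is.character(r)) {
        return(sprintf("Redundancy (%s): %s", nm, r))
      }
      c(
        sprintf(
          "Redundancy (%s): %d removal(s)%s", nm, nrow(r$removal_sequence),
          if (nrow(r$removal_sequence)) paste0(": ", paste(r$removal_sequence$variable, collapse = ", ")) else ""
        )
      )
    })),
    "",
    "## Consequences",
    "",
    bundle$amendments$markdown,
    "",
    "## Checklist coverage",
    md_table(as.data.frame(bundle$checklist)),
    if (length(plot_refs)) c("", "## Figures", paste0("![](", plot_refs, ")"))
  )
  unlist(lines[!vapply(lines, is.null, logical(1))])
}

emit_plots <- function(bundle, plot_dir) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    warn("ggplot2 not available; skipping plots.")
    return(character())
  }
  dir.create(plot_dir, showWarnings = FALSE, recursive = TRUE)
  refs <- character()
  if (!is.null(bundle$missingness$dendrogram)) {
    f <- file.path(plot_dir, "missingness_dendrogram.png")
    grDevices::png(f, width = 900, height = 700)
    plot(bundle$missingness$dendrogram$hclust,
      labels = bundle$missingness$dendrogram$annotated_labels,
      main = "Missingness discordance", xlab = "", sub = ""
    )
    grDevices::dev.off()
    refs <- c(refs, f)
  }
  if (!is.null(bundle$multivariate$clusters)) {
    f <- file.path(plot_dir, "variable_clusters.png")
    grDevices::png(f, width = 900, height = 700)
    plot(bundle$multivariate$clusters$dendrogram$hclust,
      main = "Variable clustering (1 - squared Spearman)", xlab = "", sub = ""
    )
    grDevices::dev.off()
    refs <- c(refs, f)
  }
  refs
}

# --- tidy table export -----------------------------------------------------

write_tidy_tables <- function(bundle, dir) {
  wr <- function(df, name) {
    readr::write_csv(as.data.frame(df), file.path(dir, paste0(name, ".csv")), na = "")
  }
  wr(bundle$missingness$item, "item_missingness")
  wr(bundle$missingness$cascade, "complete_case_cascade")
  wr(bundle$missingness$stratified, "stratified_complete_cases")
  cont <- bundle$univariate$continuous
  if (!is.null(cont) && nrow(cont)) {
    flat <- dplyr::select(cont, -dplyr::any_of(c("quantiles", "five_lowest", "five_highest", "top_values")))
    qs <- purrr::map_dfr(cont$quantiles, ~ as.data.frame(as.list(setNames(as.numeric(.x), paste0("q", sub("%", "", names(.x)))))))
    wr(dplyr::bind_cols(flat, qs), "continuous_summaries")
  }
  wr(bundle$transforms, "transform_decisions")
  if (!is.null(bundle$multivariate$spearman)) {
    wr(dplyr::bind_rows(
      correlation_long(bundle$multivariate$spearman),
      correlation_long(bundle$multivariate$pearson)
    ), "correlations_long")
  }
  if (nrow(bundle$findings)) {
    wr(tibble(
      rule_id = bundle$findings$rule_id,
      variables = vapply(bundle$findings$variables, paste, "", collapse = ";"),
      action = bundle$findings$action,
      severity = bundle$findings$severity
    ), "findings")
  }
  invisible(dir)
}

# --- pipeline entry point --------------------------------------------------

#' Run the screening pipeline from files to a report directory
#'
#' Reads the data, dictionary and plan, validates them, blinds the outcome
#' (unless `blind = FALSE`), runs every screening module and the
#' consequence rules, and writes `report.md` (or `.html`), the loss-free
#' `results.json`, tidy CSV tables and Newick dendrograms into the output
#' directory. On validation errors the validation report is written and a
#' nonzero status returned. Two runs with identical inputs and seed
#' produce byte-identical `results.json`.
#'
#' @param data,dictionary,plan Paths to the delimited data, delimited
#'   dictionary, and YAML plan.
#' @param out Output directory (created if absent).
#' @param blind Blind the outcome (default `TRUE`).
#' @param seed Optional seed overriding the plan's.
#' @param format Report format, `"markdown"` (default) or `"html"`.
#' @param plots Emit plot files.
#' @param quiet Suppress progress messages.
#' @return Exit status, invisibly: 0 on success, 1 on validation or module
#'   failure.
#' @export
run_ida <- function(data, dictionary, plan, out, blind = TRUE, seed = NULL,
                    format = "markdown", plots = FALSE, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  status <- tryCatch(
    {
      dict <- read_data_dictionary(dictionary)
      pl <- read_ida_plan(plan)
      if (!is.null(seed)) pl$seed <- stopifnot_scalar_int(seed, "seed")
      ds <- read_dataset(data, dict)
      say("Loaded %d rows x %d columns.", nrow(ds), ncol(ds))
      validation <- validate_plan(pl, dict, ds)
      readr::write_csv(as.data.frame(validation), file.path(out, "validation.csv"), na = "")
      if (any(validation$severity == "error")) {
        say("Plan validation failed; see validation.csv.")
        return(invisible(1L))
      }
      bundle <- ida_screen(ds, dict, pl, blind = blind, seed = seed %||% pl$seed)
      say("Screening complete; rendering.")
      json <- render_report(bundle, "json")
      writeLines(json, file.path(out, "results.json"))
      doc <- render_report(bundle, format,
        plots = plots,
        plot_dir = file.path(out, "figures")
      )
      ext <- if (format == "html") "html" else "md"
      writeLines(doc, file.path(out, paste0("report.", ext)))
      write_tidy_tables(bundle, out)
      if (!is.null(bundle$missingness$dendrogram)) {
        dendrogram_newick(bundle$missingness$dendrogram, file.path(out, "missingness_dendrogram.nwk"))
      }
      if (!is.null(bundle$multivariate$clusters)) {
        dendrogram_newick(bundle$multivariate$clusters$dendrogram, file.path(out, "variable_clusters.nwk"))
      }
      say("Wrote report to %s.", out)
      0L
    },
    error = function(e) {
      message("ida run failed: ", conditionMessage(e))
      1L
    }
  )
  invisible(status)
}
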