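#' Variable scales and roles understood by the screening toolkit
#'
#' A data dictionary assigns each variable a measurement scale and an
#' analysis role. Roles drive every downstream screening step: the single
#' `outcome` variable is only ever described univariately (and can be
#' blinded), `structural` variables (typically age and sex) stratify
#' screening outputs, `key`/`medium`/`minor` order predictors by assumed
#' importance, and `identifier` columns are excluded from all computations.
#'
#' @name dictionary-vocab
#' @keywords internal
NULL

.ida_scales <- c("continuous", "binary", "nominal", "ordinal")
.ida_roles <- c("outcome", "structural", "key", "medium", "minor", "identifier")

#' Read a data dictionary
#'
#' Reads a delimited table describing the analysis variables: one row per
#' variable with at least columns `name`, `scale` and `role`. Optional
#' columns: `label`, `units`, `lower`/`upper` (plausibility limits),
#' `component_of` (this variable is a physical component of another, e.g.
#' neutrophils are a component of the white blood count), `ratio_of` (this
#' variable is a derived percentage of another), and `collapse_map`
#' (category collapsing encoded as `"orig1=new1;orig2=new2"`).
#'
#' @param file Path or connection to a delimited text file with a header row.
#' @param delim Field delimiter, `","` by default, `"\t"` for tab.
#' @return A tibble of class `ida_dictionary`, one row per variable, with
#'   columns `name`, `label`, `scale`, `units`, `role`, `lower`, `upper`,
#'   `component_of`, `ratio_of` and a list-column `collapse_map` (named
#'   character vectors, or `NULL` where absent).
#' @export
#' @examples
#' dict_file <- system.file("extdata", "bacteremia_dictionary.csv",
#'   package = "idascreen"
#' )
#' dict <- read_data_dictionary(dict_file)
#' table(dict$role)
read_data_dictionary <- function(file, delim = ",") {
  raw <- readr::read_delim(file,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, trim_ws = TRUE, na = character()
  )
  required <- c("name", "scale", "role")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    abort(sprintf(
      "Dictionary must contain columns: %s (missing: %s).",
      paste(required, collapse = ", "), paste(missing_cols, collapse = ", ")
    ))
  }
  blank_to_na <- function(x) ifelse(is.na(x) | x == "", NA_character_, x)
  opt <- function(col) {
    if (col %in% names(raw)) blank_to_na(raw[[col]]) else rep(NA_character_, nrow(raw))
  }
  dict <- tibble(
    name = blank_to_na(raw$name),
    label = opt("label"),
    scale = blank_to_na(raw$scale),
    units = opt("units"),
    role = blank_to_na(raw$role),
    lower = suppressWarnings(as.numeric(opt("lower"))),
    upper = suppressWarnings(as.numeric(opt("upper"))),
    component_of = opt("component_of"),
    ratio_of = opt("ratio_of"),
    collapse_map = lapply(opt("collapse_map"), parse_collapse_map)
  )
  validate_dictionary(dict)
}

parse_collapse_map <- function(x) {
  if (is.na(x)) {
    return(NULL)
  }
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) abort(sprintf("Malformed collapse_map entry: '%s'.", x))
  setNames(
    vapply(kv, `[[`, "", 2L),
    trimws(vapply(kv, `[[`, "", 1L))
  )
}

format_collapse_map <- function(m) {
  if (is.null(m)) {
    return(NA_character_)
  }
  paste(paste0(names(m), "=", unname(m)), collapse = ";")
}

#' Validate a data dictionary
#'
#' Enforces the dictionary invariants: non-empty unique names, known scale
#' and role tokens, exactly one outcome variable, at least one structural
#' variable, `component_of`/`ratio_of` referencing names in the same
#' dictionary, and plausibility limits only on continuous/ordinal variables
#' with `lower <= upper`.
#'
#' @param dict A dictionary tibble as produced by [read_data_dictionary()].
#' @return The dictionary, invisibly classed as `ida_dictionary`.
#' @export
validate_dictionary <- function(dict) {
  if (any(is.na(dict$name) | dict$name == "")) {
    abort("Dictionary variable names must be non-empty.")
  }
  dup <- unique(dict$name[duplicated(dict$name)])
  if (length(dup)) {
    abort(sprintf("Duplicate variable name(s) in dictionary: %s.", paste(dup, collapse = ", ")))
  }
  bad_scale <- setdiff(unique(dict$scale), .ida_scales)
  if (length(bad_scale)) {
    abort(sprintf(
      "Unknown scale token(s): %s. Allowed: %s.",
      paste(bad_scale, collapse = ", "), paste(.ida_scales, collapse = ", ")
    ))
  }
  bad_role <- setdiff(unique(dict$role), .ida_roles)
  if (length(bad_role)) {
    abort(sprintf(
      "Unknown role token(s): %s. Allowed: %s.",
      paste(bad_role, collapse = ", "), paste(.ida_roles, collapse = ", ")
    ))
  }
  n_outcome <- sum(dict$role == "outcome")
  if (n_outcome != 1L) {
    abort(sprintf("Dictionary must declare exactly one outcome variable (found %d).", n_outcome))
  }
  if (!any(dict$role == "structural")) {
    abort("Dictionary must declare at least one structural variable.")
  }
  for (col in c("component_of", "ratio_of")) {
    refs <- dict[[col]][!is.na(dict[[col]])]
    unknown <- setdiff(refs, dict$name)
    if (length(unknown)) {
      abort(sprintf("%s references unknown variable(s): %s.", col, paste(unknown, collapse = ", ")))
    }
  }
  has_limits <- !is.na(dict$lower) | !is.na(dict$upper)
  bad_lim <- has_limits & !dict$scale %in% c("continuous", "ordinal")
  if (any(bad_lim)) {
    abort(sprintf(
      "Plausibility limits only allowed on continuous/ordinal variables: %s.",
      paste(dict$name[bad_lim], collapse = ", ")
    ))
  }
  flipped <- !is.na(dict$lower) & !is.na(dict$upper) & dict$lower > dict$upper
  if (any(flipped)) {
    abort(sprintf(
      "Plausibility limits with lower > upper: %s.",
      paste(dict$name[flipped], collapse = ", ")
    ))
  }
  class(dict) <- unique(c("ida_dictionary", "tbl_df", "tbl", "data.frame"))
  invisible(dict)
}

#' Write a data dictionary
#'
#' Inverse of [read_data_dictionary()]; writing then re-reading yields an
#' identical dictionary field by field.
#'
#' @param dict An `ida_dictionary`.
#' @param file Output path.
#' @param delim Field delimiter.
#' @export
write_data_dictionary <- function(dict, file, delim = ",") {
  out <- dict
  out$collapse_map <- vapply(dict$collapse_map, format_collapse_map, "")
  readr::write_delim(out, file, delim = delim, na = "")
  invisible(file)
}
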