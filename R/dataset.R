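#' Read an analysis dataset against a data dictionary
#'
#' Reads a delimited observations table whose header names must resolve
#' (case-sensitively) against the dictionary. Continuous and ordinal
#' variables are parsed as numerics with a `.` decimal mark regardless of
#' locale; binary/nominal variables are kept as character. Empty cells and
#' any of `na_tokens` become explicit missing values. Cells outside a
#' variable's declared plausibility limits are loaded unchanged but counted
#' (data cleaning is assumed done upstream; violations are surfaced, never
#' fixed).
#'
#' @param file Path or connection to a delimited text file with a header.
#' @param dict An `ida_dictionary`.
#' @param delim Field delimiter (`","` default).
#' @param na_tokens Character values treated as missing, besides the empty
#'   cell. Default `"NA"`.
#' @return A tibble of class `ida_dataset` with attributes
#'   `limit_violations` (tibble variable/n_violations) and `n_rows`.
#' @export
read_dataset <- function(file, dict, delim = ",", na_tokens = "NA") {
  raw <- readr::read_delim(file,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, trim_ws = TRUE, na = character(), locale = readr::locale(decimal_mark = ".")
  )
  unknown <- setdiff(names(raw), dict$name)
  if (length(unknown)) {
    abort(sprintf(
      "Data column(s) absent from the dictionary: %s.",
      paste(unknown, collapse = ", ")
    ))
  }
  if (nrow(raw) < 1L) abort("Dataset must contain at least one row.")
  ds <- raw
  for (v in names(ds)) {
    x <- ds[[v]]
    x[x %in% c("", na_tokens)] <- NA_character_
    spec <- dict[dict$name == v, ]
    if (spec$scale %in% c("continuous", "ordinal") && spec$role != "identifier") {
      num <- suppressWarnings(as.numeric(x))
      bad <- !is.na(x) & is.na(num)
      if (any(bad)) {
        abort(sprintf(
          "Variable %s declared %s but has non-numeric value(s), e.g. '%s'.",
          v, spec$scale, x[bad][1]
        ))
      }
      ds[[v]] <- num
    } else {
      ds[[v]] <- x
    }
  }
  violations <- purrr::map_int(names(ds), function(v) {
    spec <- dict[dict$name == v, ]
    if (is.na(spec$lower) && is.na(spec$upper)) {
      return(0L)
    }
    x <- ds[[v]]
    lo <- if (is.na(spec$lower)) -Inf else spec$lower
    hi <- if (is.na(spec$upper)) Inf else spec$upper
    sum(!is.na(x) & (x < lo | x > hi))
  })
  ds <- as_tibble(ds)
  attr(ds, "limit_violations") <- tibble(variable = names(ds), n_violations = violations)
  attr(ds, "n_rows") <- nrow(ds)
  class(ds) <- unique(c("ida_dataset", class(ds)))
  ds
}

#' Write an analysis dataset
#'
#' @param ds An `ida_dataset` (or plain data frame).
#' @param file Output path.
#' @param delim Field delimiter.
#' @export
write_dataset <- function(ds, file, delim = ",") {
  readr::write_delim(as_tibble(as.data.frame(ds)), file, delim = delim, na = "")
  invisible(file)
}

# Coerce a screening variable to numeric for correlation-type computations:
# continuous/ordinal pass through; binary/nominal become 0-based integer
# codes in sorted level order (two-level variables give the usual 0/1).
screening_numeric <- function(x, spec) {
  if (is.numeric(x)) {
    return(x)
  }
  lev <- sort(unique(x[!is.na(x)]))
  as.numeric(factor(x, levels = lev)) - 1
}
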