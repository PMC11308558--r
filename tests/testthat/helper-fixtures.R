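# Shared fixtures, built in code. The cached default study keeps the suite
# fast: generated once per test run at moderate size.

toy_dict <- function(extra = NULL) {
  base <- tibble::tibble(
    name = c("ID", "Y", "AGE", "SEX", "A", "B", "C"),
    label = NA_character_,
    scale = c("nominal", "binary", "continuous", "nominal", "continuous", "continuous", "continuous"),
    units = NA_character_,
    role = c("identifier", "outcome", "structural", "structural", "key", "key", "minor"),
    lower = c(NA, NA, 0, NA, NA, NA, NA),
    upper = c(NA, NA, 120, NA, NA, NA, NA),
    component_of = NA_character_,
    ratio_of = NA_character_
  )
  if (!is.null(extra)) base <- dplyr::bind_rows(base, extra)
  base$collapse_map <- vector("list", nrow(base))
  idascreen::validate_dictionary(base)
  class(base) <- unique(c("ida_dictionary", class(base)))
  base
}

toy_data <- function(n = 20, seed = 42) {
  withr::with_seed(seed, tibble::tibble(
    ID = as.character(seq_len(n)),
    Y = sample(c("no", "yes"), n, replace = TRUE, prob = c(0.9, 0.1)),
    AGE = round(runif(n, 20, 90)),
    SEX = sample(c("1", "2"), n, replace = TRUE),
    A = rnorm(n),
    B = rnorm(n),
    C = rlnorm(n)
  ))
}

as_toy_dataset <- function(tbl, dict = toy_dict()) {
  attr(tbl, "limit_violations") <- tibble::tibble(
    variable = names(tbl), n_violations = 0L
  )
  attr(tbl, "n_rows") <- nrow(tbl)
  class(tbl) <- unique(c("ida_dataset", class(tbl)))
  tbl
}

toy_plan <- function(...) {
  idascreen::ida_plan(
    model_sets = list(key = c("AGE", "SEX", "A", "B"), all = c("AGE", "SEX", "A", "B", "C")),
    ...
  )
}

# Write a small delimited file and return its path.
write_fixture <- function(lines, ext = ".csv") {
  f <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# Default bacteremia-like study, cached per session (n kept moderate so the
# multivariate stages stay fast).
.study_cache <- new.env(parent = emptyenv())
default_study <- function(n_rows = 1200, seed = 1) {
  key <- sprintf("n%d_s%d", n_rows, seed)
  if (is.null(.study_cache[[key]])) {
    .study_cache[[key]] <- idascreen::generate_synthetic_study(
      idascreen::default_bacteremia_like_spec(seed = seed, n_rows = n_rows)
    )
  }
  .study_cache[[key]]
}

default_bundle <- function(n_rows = 1200, seed = 1) {
  key <- sprintf("bundle_n%d_s%d", n_rows, seed)
  if (is.null(.study_cache[[key]])) {
    st <- default_study(n_rows, seed)
    .study_cache[[key]] <- idascreen::ida_screen(st$data, st$dictionary, st$plan)
  }
  .study_cache[[key]]
}
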