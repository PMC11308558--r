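# Internal helpers shared across modules.

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards. All randomness in the package funnels through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# md5 digest of an arbitrary R object, via serialization to a temp file
# (base R exposes md5 only for files).
object_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2L)
  close(con)
  unname(tools::md5sum(f))
}

is_missing_cell <- function(x) is.na(x)

# Variables that take part in screening computations: everything except
# identifiers. The outcome is screened univariately only.
screening_variables <- function(dict) {
  dict$name[dict$role != "identifier"]
}

predictor_variables <- function(dict) {
  dict$name[!dict$role %in% c("identifier", "outcome")]
}

continuous_variables <- function(dict) {
  dict$name[dict$scale %in% c("continuous", "ordinal") &
    !dict$role %in% c("identifier", "outcome")]
}

stopifnot_scalar_int <- function(x, what) {
  if (length(x) != 1L || is.na(x) || x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer.", what))
  }
  as.integer(x)
}
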