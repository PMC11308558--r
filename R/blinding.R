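#' Blind the outcome by seeded permutation
#'
#' Produces the outcome-blinded screening dataset: the single outcome column
#' (values and missing cells together, as a unit) is permuted by a seeded
#' uniform random permutation while every predictor column is left
#' untouched. Any predictor-outcome association is thereby destroyed while
#' the outcome's marginal distribution - including its item-missingness
#' proportion - and all between-predictor structure are preserved. This
#' imitates a blinded data review in clinical trials.
#'
#' @param ds An `ida_dataset`.
#' @param dict An `ida_dictionary` identifying exactly one outcome column.
#' @param seed Integer seed; identical `(ds, seed)` give the identical
#'   permuted column.
#' @return A list with elements `data` (the blinded dataset) and `record`
#'   (a `blinding_record`: seed, md5 checksum of the applied permutation,
#'   timestamp).
#' @export
#' @examples
#' study <- generate_synthetic_study(default_bacteremia_like_spec(seed = 1, n_rows = 50))
#' b <- blind_outcome(study$data, study$dictionary, seed = 7)
#' identical(sort(b$data$BloodCulture), sort(study$data$BloodCulture))
blind_outcome <- function(ds, dict, seed) {
  outcome <- dict$name[dict$role == "outcome"]
  if (length(outcome) != 1L || !outcome %in% names(ds)) {
    abort("Dataset must contain exactly one outcome column to blind.")
  }
  seed <- stopifnot_scalar_int(seed, "seed")
  n <- nrow(ds)
  perm <- with_seed(seed, sample.int(n))
  blinded <- ds
  blinded[[outcome]] <- ds[[outcome]][perm]
  record <- structure(
    list(
      seed = seed,
      permutation_checksum = object_md5(perm),
      outcome = outcome,
      timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
    ),
    class = "blinding_record"
  )
  list(data = blinded, record = record)
}
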