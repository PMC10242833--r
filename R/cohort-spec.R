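#' Build an item table for a two-instrument cohort
#'
#' Convenience constructor for the item side of a [cohort_spec()]: `n_ados`
#' observation items plus `n_adir` caregiver-interview items, with a chosen
#' subset of each block made discriminative through a proportional-odds
#' location shift.
#'
#' @param n_ados,n_adir Number of ADOS / ADI-R items.
#' @param informative_ados,informative_adir Indices (within each block) of
#'   the items that receive `shift`; the rest are non-informative.
#' @param shift Ordered-logit location shift for the informative items.
#' @param n_levels Number of ordinal codes per item (default 3, i.e. codes
#'   0/1/2 as in clinical item algorithms).
#' @return A tibble with columns `item_id`, `instrument`, `n_levels`,
#'   `shift`, usable as the `items` field of [cohort_spec()].
#' @examples
#' instrument_items(29, 31, informative_ados = 1:5, informative_adir = 1:5)
#' @export
instrument_items <- function(n_ados, n_adir,
                             informative_ados = integer(),
                             informative_adir = integer(),
                             shift = 1.5, n_levels = 3) {
  stopifnot(n_ados >= 0, n_adir >= 0, n_ados + n_adir >= 1)
  shifts_ados <- rep(0, n_ados)
  shifts_ados[informative_ados] <- shift
  shifts_adir <- rep(0, n_adir)
  shifts_adir[informative_adir] <- shift
  tibble::tibble(
    item_id = c(sprintf("ados_%02d", seq_len(n_ados)),
                sprintf("adir_%02d", seq_len(n_adir))),
    instrument = rep(c("ADOS", "ADI_R"), c(n_ados, n_adir)),
    n_levels = as.integer(n_levels),
    shift = c(shifts_ados, shifts_adir)
  )
}

#' Specify a synthetic two-group cohort
#'
#' A cohort spec fixes everything [generate_cohort()] needs: group sizes, the
#' item table (one proportional-odds item per row), the per-subject
#' probability that the whole ADI-R block is missing (interview never done),
#' and the seed.
#'
#' @param n_asd,n_nonasd Subjects per diagnostic group (both >= 1).
#' @param items Tibble with columns `item_id`, `instrument` (`"ADOS"` or
#'   `"ADI_R"`), `n_levels` (>= 2), `shift` (finite, >= 0); see
#'   [instrument_items()].
#' @param adi_missing_fraction Probability in `[0, 1]` that a subject is
#'   missing all ADI-R items (block-wise, all-or-none).
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return An object of class `cohort_spec`.
#' @seealso [default_cohort_spec()], [generate_cohort()]
#' @export
cohort_spec <- function(n_asd, n_nonasd, items,
                        adi_missing_fraction = 0, seed = 1L) {
  if (!is.numeric(n_asd) || length(n_asd) != 1 || is.na(n_asd) || n_asd < 1) {
    abort("`n_asd` must be a single integer >= 1")
  }
  if (!is.numeric(n_nonasd) || length(n_nonasd) != 1 || is.na(n_nonasd) || n_nonasd < 1) {
    abort("`n_nonasd` must be a single integer >= 1")
  }
  items <- tibble::as_tibble(items)
  required <- c("item_id", "instrument", "n_levels", "shift")
  missing_cols <- setdiff(required, names(items))
  if (length(missing_cols) > 0) {
    abort(paste0("`items` is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(items) == 0) abort("`items` must contain at least one item")
  if (anyDuplicated(items$item_id)) {
    abort(paste0("`items` has duplicated item_id: ",
                 paste(unique(items$item_id[duplicated(items$item_id)]), collapse = ", ")))
  }
  if (!all(items$instrument %in% c("ADOS", "ADI_R"))) {
    abort("`items` column `instrument` must be \"ADOS\" or \"ADI_R\"")
  }
  if (any(items$n_levels < 2)) abort("`items` column `n_levels` must be >= 2 for every item")
  if (any(!is.finite(items$shift) | items$shift < 0)) {
    abort("`items` column `shift` must be finite and >= 0 for every item")
  }
  if (!is.numeric(adi_missing_fraction) || length(adi_missing_fraction) != 1 ||
      is.na(adi_missing_fraction) ||
      adi_missing_fraction < 0 || adi_missing_fraction > 1) {
    abort("`adi_missing_fraction` must be a single number in [0, 1]")
  }
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("`seed` must be a single integer")
  }
  structure(
    list(
      n_asd = as.integer(n_asd),
      n_nonasd = as.integer(n_nonasd),
      items = dplyr::mutate(items, n_levels = as.integer(.data$n_levels)),
      adi_missing_fraction = adi_missing_fraction,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  cat(sprintf("  subjects: %d ASD + %d non-ASD\n", x$n_asd, x$n_nonasd))
  cat(sprintf("  items: %d (%d ADOS, %d ADI-R), %d informative (shift > 0)\n",
              nrow(x$items), sum(x$items$instrument == "ADOS"),
              sum(x$items$instrument == "ADI_R"), sum(x$items$shift > 0)))
  cat(sprintf("  ADI-R block missingness: %.2f   seed: %d\n",
              x$adi_missing_fraction, x$seed))
  invisible(x)
}

#' Reference synthetic cohorts
#'
#' `default_cohort_spec()` is the package's standard benchmark cohort:
#' 250 subjects per group, 60 items (29 ADOS + 31 ADI-R) of which 10 are
#' informative at shift 1.5 (5 in each instrument block), no missingness.
#' `null_cohort_spec()` is the same cohort with every shift set to 0, used
#' for type-I-error calibration.
#'
#' @param seed Integer seed passed to [cohort_spec()].
#' @param adi_missing_fraction Optional ADI-R block missingness.
#' @return A [cohort_spec()].
#' @export
default_cohort_spec <- function(seed = 1L, adi_missing_fraction = 0) {
  cohort_spec(
    n_asd = 250, n_nonasd = 250,
    items = instrument_items(29, 31,
                             informative_ados = 1:5, informative_adir = 1:5,
                             shift = 1.5, n_levels = 3),
    adi_missing_fraction = adi_missing_fraction,
    seed = seed
  )
}

#' @rdname default_cohort_spec
#' @export
null_cohort_spec <- function(seed = 1L, adi_missing_fraction = 0) {
  spec <- default_cohort_spec(seed = seed, adi_missing_fraction = adi_missing_fraction)
  spec$items$shift <- 0
  spec
}
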