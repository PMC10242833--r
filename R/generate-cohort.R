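#' Generate a synthetic two-group ordinal-item cohort
#'
#' Draws every subject's code on every item independently from the item's
#' proportional-odds model (see [ordinal_item_probs()]): non-ASD subjects
#' from the baseline distribution, ASD subjects from the shifted one. When
#' `adi_missing_fraction > 0`, a seeded Bernoulli draw per subject removes
#' the entire ADI-R block (all-or-none, mirroring interview-level
#' availability); ADOS items are never missing.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per subject: `subject_id`, `label`
#'   (factor `NON_ASD`/`ASD`), then one integer column per item (`NA` =
#'   missing). The item table travels along as attribute `"item_meta"`;
#'   retrieve it with [cohort_items()].
#' @examples
#' cohort <- generate_cohort(default_cohort_spec(seed = 42))
#' dplyr::count(cohort, label)
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    spec <- do.call(cohort_spec, spec)  # validate plain lists
  }
  n <- spec$n_asd + spec$n_nonasd
  label <- as_class_factor(rep(c("ASD", "NON_ASD"), c(spec$n_asd, spec$n_nonasd)))
  out <- tibble::tibble(
    subject_id = sprintf("S%04d", seq_len(n)),
    label = label
  )
  asd <- label == "ASD"
  withr::with_seed(spec$seed, {
    for (i in seq_len(nrow(spec$items))) {
      it <- spec$items[i, ]
      p <- ordinal_item_probs(it$n_levels, it$shift)
      codes <- integer(n)
      codes[asd] <- sample(p$code, sum(asd), replace = TRUE, prob = p$p_asd)
      codes[!asd] <- sample(p$code, sum(!asd), replace = TRUE, prob = p$p_nonasd)
      out[[it$item_id]] <- codes
    }
    adir_ids <- spec$items$item_id[spec$items$instrument == "ADI_R"]
    if (spec$adi_missing_fraction > 0 && length(adir_ids) > 0) {
      drop <- runif(n) < spec$adi_missing_fraction
      for (id in adir_ids) out[[id]][drop] <- NA_integer_
    }
  })
  attr(out, "item_meta") <- spec$items
  out
}

#' Item metadata attached to a cohort
#'
#' @param data A cohort tibble from [generate_cohort()] or [read_cohort()].
#' @return The item metadata tibble (`item_id`, `instrument`, `n_levels`,
#'   `shift` where known).
#' @export
cohort_items <- function(data) {
  meta <- attr(data, "item_meta")
  if (is.null(meta)) {
    abort("`data` carries no \"item_meta\" attribute; build it with generate_cohort() or read_cohort()")
  }
  meta
}

#' Feature universe of a cohort
#'
#' Returns the item ids belonging to a feature universe: `"combined"` (all
#' items) or `"ados_only"` (ADOS-instrument items alone).
#'
#' @param data A cohort tibble carrying item metadata.
#' @param universe `"combined"` or `"ados_only"`.
#' @return Character vector of item ids, in item-table order.
#' @export
feature_universe <- function(data, universe = c("combined", "ados_only")) {
  universe <- match.arg(universe)
  meta <- cohort_items(data)
  if (universe == "ados_only") meta$item_id[meta$instrument == "ADOS"] else meta$item_id
}

#' Drop subjects with any missing feature
#'
#' Complete-case policy: subjects missing any item of the active feature
#' universe are removed before splitting and modelling.
#'
#' @param data A cohort tibble.
#' @param features Item ids to require; defaults to all items.
#' @return The filtered tibble (attributes preserved).
#' @export
filter_complete_cases <- function(data, features = feature_universe(data)) {
  missing_cols <- setdiff(features, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("features absent from `data`: ", paste(missing_cols, collapse = ", ")))
  }
  keep <- complete.cases(data[features])
  out <- data[keep, , drop = FALSE]
  attr(out, "item_meta") <- attr(data, "item_meta")
  out
}
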