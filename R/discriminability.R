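# midrank (tie-aware) two-sample AUC of a score for ASD vs non-ASD;
# equals the normalised Wilcoxon rank-sum statistic
rank_auc <- function(score, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) {
    abort("AUC is undefined: both classes must be present")
  }
  r <- rank(score)  # midranks for ties
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Single-item discriminability (rank AUC)
#'
#' Two-sample AUC of one item's ordinal codes for ASD versus non-ASD, with
#' ties handled by midranks: the probability that a random ASD subject codes
#' higher than a random non-ASD subject, counting ties as one half. Missing
#' codes are dropped; an item with no non-missing code in one class is a
#' degenerate input.
#'
#' @param data A cohort tibble with a `label` column.
#' @param item_id Item column to assess.
#' @return A single AUC in `[0, 1]`.
#' @examples
#' cohort <- generate_cohort(default_cohort_spec(seed = 7))
#' single_item_discriminability(cohort, "ados_01")
#' @export
single_item_discriminability <- function(data, item_id) {
  if (!item_id %in% names(data)) abort(paste0("item not present: ", item_id))
  codes <- data[[item_id]]
  lab <- as_class_factor(data$label)
  keep <- !is.na(codes)
  codes <- codes[keep]
  lab <- lab[keep]
  if (!all(.classes %in% lab)) {
    missing_class <- setdiff(.classes, as.character(unique(lab)))
    abort(paste0("all codes of ", item_id, " are missing for class ",
                 paste(missing_class, collapse = ", ")))
  }
  rank_auc(codes, lab == "ASD")
}

#' Discriminability of every item in a cohort
#'
#' @param data A cohort tibble with a `label` column.
#' @param items Item ids to assess; defaults to all items in the metadata.
#' @return A tibble `item_id`, `auc`, sorted as supplied.
#' @export
item_discriminability <- function(data, items = feature_universe(data)) {
  tibble::tibble(
    item_id = items,
    auc = purrr::map_dbl(items, \(id) single_item_discriminability(data, id))
  )
}
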