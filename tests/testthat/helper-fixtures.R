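# Small, fast cohort used by unit tests: 12 items (6 + 6), 4 informative at
# shift 2, 60 subjects per group. Signal is strong so recovery is easy at
# desk scale; the full-size benchmark cohort lives in default_cohort_spec().
small_spec <- function(seed = 1L, adi_missing_fraction = 0) {
  cohort_spec(
    n_asd = 60, n_nonasd = 60,
    items = instrument_items(6, 6, informative_ados = 1:2, informative_adir = 1:2,
                             shift = 2, n_levels = 3),
    adi_missing_fraction = adi_missing_fraction,
    seed = seed
  )
}

fast_rf <- function(seed = 1L, n_trees = 60) {
  rf_config(n_trees = n_trees, importance_repeats = 2, seed = seed)
}

fast_selection <- function(seed = 1L, ...) {
  selection_config(rf = fast_rf(seed), ...)
}

informative_items <- function(spec) spec$items$item_id[spec$items$shift > 0]

# brute-force AUC: all class pairs, ties count one half
pair_auc <- function(scores_pos, scores_neg) {
  wins <- 0
  for (a in scores_pos) for (b in scores_neg) {
    wins <- wins + (a > b) + 0.5 * (a == b)
  }
  wins / (length(scores_pos) * length(scores_neg))
}
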