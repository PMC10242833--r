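#' Random-forest configuration
#'
#' Hyperparameters of the majority-vote tree ensemble. Defaults follow
#' common random-forest practice: 500 trees, square-root-of-p candidate
#' features per split, leaves grown to a single subject, and 5 permutation
#' repeats for the importance computation.
#'
#' @param n_trees Number of trees (>= 1).
#' @param features_per_split `"sqrt"` for the square-root rule or an
#'   integer number of candidate features per split.
#' @param min_leaf Minimal terminal-node size.
#' @param importance_repeats Number of independent feature permutations
#'   averaged in [rf_importance()] (>= 1).
#' @param seed Integer seed making fitting, prediction and importance
#'   deterministic.
#' @return An object of class `rf_config`.
#' @export
rf_config <- function(n_trees = 500, features_per_split = "sqrt",
                      min_leaf = 1, importance_repeats = 5, seed = 1L) {
  if (!is.numeric(n_trees) || n_trees < 1) abort("`n_trees` must be >= 1")
  if (!is.numeric(importance_repeats) || importance_repeats < 1) {
    abort("`importance_repeats` must be >= 1")
  }
  if (!(identical(features_per_split, "sqrt") ||
        (is.numeric(features_per_split) && features_per_split >= 1))) {
    abort("`features_per_split` must be \"sqrt\" or an integer >= 1")
  }
  structure(
    list(n_trees = as.integer(n_trees), features_per_split = features_per_split,
         min_leaf = as.integer(min_leaf),
         importance_repeats = as.integer(importance_repeats),
         seed = as.integer(seed)),
    class = "rf_config"
  )
}

resolve_mtry <- function(config, p) {
  if (identical(config$features_per_split, "sqrt")) {
    max(1L, floor(sqrt(p)))
  } else {
    min(as.integer(config$features_per_split), p)
  }
}

check_rf_input <- function(data, features) {
  missing_cols <- setdiff(features, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("feature column(s) absent from `data`: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(!complete.cases(data[features]))) {
    abort("`data` contains missing feature values; apply filter_complete_cases() first")
  }
}

#' Fit a majority-vote random forest
#'
#' Trains a classification forest (via the ranger engine) on the given item
#' columns; each tree votes a class and the ensemble's score for a subject
#' is its ASD vote fraction. Fitting is deterministic given the data,
#' feature set and `config$seed`. Subjects with missing feature values must
#' be excluded beforehand ([filter_complete_cases()]).
#'
#' @param data Cohort tibble (rows = training subjects) with a `label`
#'   column coded `ASD` / `NON_ASD`.
#' @param features Character vector of item columns to use.
#' @param config An [rf_config()].
#' @return An object of class `rf_model` holding the fitted ensemble, the
#'   feature ids, training size and the configuration.
#' @export
rf_fit <- function(data, features, config = rf_config()) {
  check_rf_input(data, features)
  y <- as_class_factor(data$label)
  if (length(unique(y)) < 2 || nrow(data) == 0) {
    abort("degenerate training set: need at least one subject of each class")
  }
  x <- as.data.frame(data[features], check.names = FALSE)
  fit <- ranger::ranger(
    x = x, y = y,
    num.trees = config$n_trees,
    mtry = resolve_mtry(config, length(features)),
    min.node.size = config$min_leaf,
    keep.inbag = TRUE,
    seed = config$seed,
    num.threads = 1
  )
  structure(
    list(fit = fit, features = features, n_train = nrow(data), config = config,
         asd_code = match("ASD", fit$forest$levels)),
    class = "rf_model"
  )
}

#' @export
print.rf_model <- function(x, ...) {
  cat(sprintf("<rf_model> %d trees, %d features, %d training subjects\n",
              x$config$n_trees, length(x$features), x$n_train))
  invisible(x)
}

# n x n_trees matrix of per-tree ASD votes (logical)
tree_votes <- function(model, data) {
  pred <- ranger::predictions(
    stats::predict(model$fit, data = as.data.frame(data[model$features], check.names = FALSE),
                   predict.all = TRUE, num.threads = 1)
  )
  pred == model$asd_code
}

#' Vote-fraction scores of a fitted forest
#'
#' @param model An [rf_fit()] model.
#' @param data Cohort tibble containing the model's feature columns
#'   (complete cases).
#' @return A tibble `subject_id` (if present in `data`), `score` — the
#'   fraction of trees voting ASD, in `[0, 1]`; the ensemble's majority
#'   call is `score >= 0.5` up to exact ties.
#' @export
rf_predict_scores <- function(model, data) {
  check_rf_input(data, model$features)
  score <- rowMeans(tree_votes(model, data))
  if ("subject_id" %in% names(data)) {
    tibble::tibble(subject_id = data$subject_id, score = score)
  } else {
    tibble::tibble(score = score)
  }
}

#' Permutation importance ranking (mean decrease in accuracy)
#'
#' Fits a forest and measures, for every feature, the mean drop in per-tree
#' out-of-bag accuracy when that feature's column is permuted, averaged over
#' `config$importance_repeats` independent permutations and all trees.
#' Features are ranked by importance, ties broken by their input order, so
#' the ranking is a deterministic total order.
#'
#' @inheritParams rf_fit
#' @return A tibble of class `importance_ranking` with columns `rank`,
#'   `item_id`, `importance`, sorted by decreasing importance.
#' @examples
#' cohort <- generate_cohort(default_cohort_spec(seed = 3))
#' rk <- rf_importance(cohort, feature_universe(cohort),
#'                     rf_config(n_trees = 100, importance_repeats = 2))
#' head(rk)
#' @export
rf_importance <- function(data, features, config = rf_config()) {
  model <- rf_fit(data, features, config)
  y_asd <- as_class_factor(data$label) == "ASD"
  inbag <- simplify2array(model$fit$inbag.counts)   # n x n_trees
  oob <- inbag == 0
  oob_n <- colSums(oob)
  use_tree <- oob_n > 0
  votes0 <- tree_votes(model, data)
  base_acc <- colSums((votes0 == y_asd) & oob)[use_tree] / oob_n[use_tree]
  n <- nrow(data)
  drop_sum <- numeric(length(features))
  withr::with_seed(config$seed + 1L, {
    for (r in seq_len(config$importance_repeats)) {
      perm <- sample.int(n)
      for (j in seq_along(features)) {
        d <- data[features]
        d[[j]] <- d[[j]][perm]
        votes <- tree_votes(model, d)
        acc <- colSums((votes == y_asd) & oob)[use_tree] / oob_n[use_tree]
        drop_sum[j] <- drop_sum[j] + mean(base_acc - acc)
      }
    }
  })
  importance <- drop_sum / config$importance_repeats
  ord <- order(-importance, seq_along(features))
  out <- tibble::tibble(
    rank = seq_along(features),
    item_id = features[ord],
    importance = importance[ord]
  )
  class(out) <- c("importance_ranking", class(out))
  out
}
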