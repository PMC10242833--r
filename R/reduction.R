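#' Selection configuration
#'
#' Parameters of the accuracy-versus-complexity model selection: the
#' weighted score is `w1 * validation AUC + w2 * complexity(k)` with the
#' defaults `w1 = 0.35`, `w2 = 0.65` weighting simplicity over accuracy in
#' a 2:1 ratio. `alpha` is the level of the McNemar equivalence screen that
#' defines the minimal model.
#'
#' @param w1,w2 Non-negative weights on validation AUC and complexity;
#'   must sum to 1.
#' @param alpha McNemar significance level in (0, 1).
#' @param complexity_normalization `"linear_inverse"` or `"rank_based"`;
#'   see [complexity()].
#' @param threshold Classification threshold on the vote-fraction score.
#' @param rf An [rf_config()] shared by ranking and all model fits.
#' @param mcnemar_method Method passed to [mcnemar_compare()].
#' @param cv_scheme Cross-validation scheme for [make_split()].
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(w1 = 0.35, w2 = 0.65, alpha = 0.05,
                             complexity_normalization = c("linear_inverse", "rank_based"),
                             threshold = 0.5, rf = rf_config(),
                             mcnemar_method = "auto",
                             cv_scheme = c("partition", "resample")) {
  if (abs(w1 + w2 - 1) > 1e-8 || w1 < 0 || w2 < 0) {
    abort("`w1` and `w2` must be non-negative and sum to 1")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1)")
  structure(
    list(w1 = w1, w2 = w2, alpha = alpha,
         complexity_normalization = match.arg(complexity_normalization),
         threshold = threshold, rf = rf, mcnemar_method = mcnemar_method,
         cv_scheme = match.arg(cv_scheme)),
    class = "selection_config"
  )
}

#' Complexity term of the weighted model score
#'
#' Maps a model's feature count onto `[0, 1]` so it is commensurate with
#' AUC; higher means simpler under both normalizations.
#' `linear_inverse` (default) is `1 - (k - 1) / (N - 1)`, spanning exactly
#' 1 at `k = 1` down to 0 at `k = N`. `rank_based` is the fraction of the
#' `N` candidate models having at least `k` features, minus a `1/N` offset
#' so the largest model scores 0, i.e. `(N - k) / N`.
#'
#' @param k Feature count(s), `1 <= k <= N`.
#' @param N Total number of candidate features (>= 2).
#' @param normalization `"linear_inverse"` or `"rank_based"`.
#' @return Numeric vector of complexity scores in `[0, 1]`.
#' @examples
#' complexity(1, 66)                 # 1
#' complexity(18, 66)                # 1 - 17/65
#' complexity(66, 66)                # 0
#' @export
complexity <- function(k, N, normalization = c("linear_inverse", "rank_based")) {
  normalization <- match.arg(normalization)
  if (!is.numeric(N) || length(N) != 1 || N < 2) {
    abort("`N` must be a single integer >= 2")
  }
  if (any(k < 1 | k > N)) abort("`k` must satisfy 1 <= k <= N")
  if (normalization == "linear_inverse") {
    1 - (k - 1) / (N - 1)
  } else {
    (N - k) / N
  }
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("stage ", stage, ": ", conditionMessage(e)))
  })
}

fit_and_score <- function(train, newdata, features, rf, threshold) {
  model <- rf_fit(train, features, rf)
  scores <- rf_predict_scores(model, newdata)
  tibble::tibble(
    subject_id = newdata$subject_id,
    label = as_class_factor(newdata$label),
    score = scores$score,
    pred = ifelse(scores$score >= threshold, "ASD", "NON_ASD")
  )
}

#' Evaluate one reduced-feature model
#'
#' Takes the top-`k` prefix of an importance ranking and evaluates it two
#' ways: (i) cross-validated testing — one forest per fold, trained on the
#' fold's training subjects and scored on its test subjects, with the fold
#' performance summaries averaged; (ii) a single forest refit on the whole
#' development portion and scored on the held-out validation subjects. The
#' weighted score combines the validation AUC with the model's
#' [complexity()].
#'
#' @param data Cohort tibble (complete cases over the ranked features).
#' @param ranking An [rf_importance()] ranking (or tibble with `item_id`
#'   in rank order).
#' @param k Prefix length, `1 <= k <= nrow(ranking)`.
#' @param plan A [make_split()] plan for `data`.
#' @param config A [selection_config()].
#' @param cv Run the cross-validated fold testing? With `cv = FALSE` only
#'   the validation refit is computed and the `test_summary` is `NA` —
#'   useful for calibration experiments that only read validation
#'   quantities.
#' @return An object of class `model_evaluation`: `k`, `feature_ids`,
#'   `test_summary` and `validation_summary` (one-row [performance()]
#'   tibbles), `validation_predictions` (per-subject calls and scores) and
#'   `weighted_score`.
#' @export
evaluate_reduced_model <- function(data, ranking, k, plan, config = selection_config(),
                                   cv = TRUE) {
  N <- nrow(ranking)
  if (k < 1 || k > N) abort(paste0("`k` must lie in 1..", N))
  feats <- ranking$item_id[seq_len(k)]
  rows <- function(ids) data[match(ids, data$subject_id), , drop = FALSE]
  test_summary <- if (cv) {
    fold_perf <- purrr::imap(plan$folds, function(fold, i) {
      with_stage(paste0("fold ", i, " (k = ", k, ")"), {
        rf <- config$rf
        rf$seed <- rf$seed + i
        performance(fit_and_score(rows(fold$train_ids), rows(fold$test_ids),
                                  feats, rf, config$threshold),
                    score = score, threshold = config$threshold)
      })
    })
    dplyr::summarise(
      dplyr::bind_rows(fold_perf),
      dplyr::across(c("auc", "acc", "sensitivity", "specificity", "youden_j"), mean),
      n = sum(.data$n)
    )
  } else {
    tibble::tibble(auc = NA_real_, acc = NA_real_, sensitivity = NA_real_,
                   specificity = NA_real_, youden_j = NA_real_, n = NA_integer_)
  }
  val_pred <- with_stage(paste0("validation refit (k = ", k, ")"),
    fit_and_score(rows(plan$development_ids), rows(plan$validation_ids),
                  feats, config$rf, config$threshold))
  validation_summary <- performance(val_pred, score = score, threshold = config$threshold)
  structure(
    list(
      k = as.integer(k),
      feature_ids = feats,
      test_summary = test_summary,
      validation_summary = validation_summary,
      validation_predictions = val_pred,
      weighted_score = config$w1 * validation_summary$auc +
        config$w2 * complexity(k, N, config$complexity_normalization)
    ),
    class = "model_evaluation"
  )
}

#' Stepwise reduced-model selection
#'
#' The package's core procedure, run on a fixed development/validation
#' split: (1) rank all features by out-of-bag permutation importance on the
#' development portion; (2) train stepwise reduced models on the ranking
#' prefixes `k = 1..N` under cross-validation; (3) refit each prefix on the
#' full development portion, evaluate it on the held-out validation
#' subjects, and score it by `w1 * AUC + w2 * complexity`; (4) compare each
#' reduced model's validation predictions against the full-feature model
#' with McNemar's test. The *optimal* model maximizes the weighted score
#' (ties to the smaller `k`); the *minimal* model is the smallest `k`
#' whose McNemar p-value is at least `alpha`.
#'
#' @param data Cohort tibble, complete cases over `features`.
#' @param plan A [make_split()] plan; built from `seed` when omitted.
#' @param config A [selection_config()].
#' @param features Feature universe (item ids); defaults to every item in
#'   the cohort metadata.
#' @param ks Feature counts to evaluate (default `1:N`; `N` is always
#'   included). Restricting `ks` thins the curve but keeps the contract.
#' @param seed Seed for [make_split()] when `plan` is omitted.
#' @param cv Passed to [evaluate_reduced_model()].
#' @return An object of class `selection_report`; see [tidy()], [glance()]
#'   and [autoplot()] methods.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(default_cohort_spec(seed = 11))
#' cfg <- selection_config(rf = rf_config(n_trees = 100, importance_repeats = 2))
#' rep <- select_models(cohort, config = cfg, seed = 11, ks = c(1, 5, 10, 30, 60))
#' glance(rep)
#' }
#' @export
select_models <- function(data, plan = NULL, config = selection_config(),
                          features = feature_universe(data), ks = NULL,
                          seed = NULL, cv = TRUE) {
  if (any(!complete.cases(data[features]))) {
    abort("stage input: `data` has missing values in the feature universe; apply filter_complete_cases()")
  }
  if (is.null(plan)) {
    if (is.null(seed)) abort("provide either `plan` or `seed`")
    plan <- with_stage("split", make_split(data, seed, scheme = config$cv_scheme))
  }
  N <- length(features)
  ks <- if (is.null(ks)) seq_len(N) else sort(unique(c(as.integer(ks), N)))
  if (any(ks < 1 | ks > N)) abort(paste0("`ks` must lie in 1..", N))
  dev <- data[match(plan$development_ids, data$subject_id), , drop = FALSE]
  ranking <- with_stage("ranking", rf_importance(dev, features, config$rf))
  evals <- purrr::map(ks, \(k) evaluate_reduced_model(data, ranking, k, plan, config, cv = cv))
  names(evals) <- as.character(ks)
  full <- evals[[as.character(N)]]
  mcn <- purrr::map(evals, function(ev) {
    with_stage(paste0("mcnemar (k = ", ev$k, ")"), {
      df <- dplyr::inner_join(
        dplyr::select(ev$validation_predictions, "subject_id", "label", pred_k = "pred"),
        dplyr::select(full$validation_predictions, "subject_id", pred_full = "pred"),
        by = "subject_id"
      )
      mcnemar_compare(df, pred_a = .data$pred_k, pred_b = .data$pred_full,
                      method = config$mcnemar_method)
    })
  })
  evaluations <- dplyr::bind_rows(purrr::map2(evals, mcn, function(ev, m) {
    tibble::tibble(
      k = ev$k,
      test_auc = ev$test_summary$auc, test_acc = ev$test_summary$acc,
      test_sensitivity = ev$test_summary$sensitivity,
      test_specificity = ev$test_summary$specificity,
      test_youden_j = ev$test_summary$youden_j,
      val_auc = ev$validation_summary$auc, val_acc = ev$validation_summary$acc,
      val_sensitivity = ev$validation_summary$sensitivity,
      val_specificity = ev$validation_summary$specificity,
      val_youden_j = ev$validation_summary$youden_j,
      complexity = complexity(ev$k, N, config$complexity_normalization),
      weighted_score = ev$weighted_score,
      mcnemar_b = m$b, mcnemar_c = m$c, mcnemar_statistic = m$statistic,
      mcnemar_p = m$p_value, mcnemar_method = m$method
    )
  }))
  ord <- order(-evaluations$weighted_score, evaluations$k)
  optimal_k <- evaluations$k[ord[1]]
  equiv <- evaluations$k[evaluations$mcnemar_p >= config$alpha]
  minimal_k <- if (length(equiv) > 0) min(equiv) else NA_integer_
  structure(
    list(
      ranking = ranking,
      evaluations = evaluations,
      models = evals,
      optimal_k = optimal_k,
      minimal_k = minimal_k,
      n_features = N,
      features = features,
      plan = plan,
      config = config,
      seed = plan$seed
    ),
    class = "selection_report"
  )
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> %d candidate features, %d models evaluated\n",
              x$n_features, nrow(x$evaluations)))
  cat(sprintf("  optimal model: k = %d (weighted score %.3f)\n", x$optimal_k,
              max(x$evaluations$weighted_score)))
  if (is.na(x$minimal_k)) {
    cat("  minimal model: none (no k McNemar-equivalent to the full model)\n")
  } else {
    cat(sprintf("  minimal model: k = %d (McNemar p = %.3f vs full)\n", x$minimal_k,
                x$evaluations$mcnemar_p[x$evaluations$k == x$minimal_k]))
  }
  invisible(x)
}

#' @describeIn select_models Per-model metrics table (one row per evaluated
#'   feature count).
#' @param x A `selection_report`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.selection_report <- function(x, ...) x$evaluations

#' @describeIn select_models One-row summary: split sizes, optimal and
#'   minimal feature counts and their validation AUCs.
#' @exportS3Method generics::glance
glance.selection_report <- function(x, ...) {
  ev <- x$evaluations
  pick <- function(k, col) if (is.na(k)) NA_real_ else ev[[col]][ev$k == k]
  tibble::tibble(
    n_features = x$n_features,
    n_development = length(x$plan$development_ids),
    n_validation = length(x$plan$validation_ids),
    optimal_k = x$optimal_k,
    minimal_k = x$minimal_k,
    full_val_auc = pick(x$n_features, "val_auc"),
    optimal_val_auc = pick(x$optimal_k, "val_auc"),
    minimal_val_auc = pick(x$minimal_k, "val_auc"),
    optimal_weighted_score = pick(x$optimal_k, "weighted_score"),
    minimal_mcnemar_p = pick(x$minimal_k, "mcnemar_p")
  )
}
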