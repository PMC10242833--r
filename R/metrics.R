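offending_ids <- function(data, bad) {
  if ("subject_id" %in% names(data)) {
    paste(head(data$subject_id[bad], 10), collapse = ", ")
  } else {
    paste(head(which(bad), 10), collapse = ", ")
  }
}

#' Confusion counts for binary diagnostic predictions
#'
#' Cross-tabulates true labels against predicted class calls with ASD as the
#' positive class. Every labelled subject must carry a prediction: a missing
#' call is a coverage error, reported with the offending subject ids.
#'
#' @param data Data frame with one row per subject.
#' @param truth,estimate Columns (tidy-eval) holding the true label and the
#'   predicted call, both coded `ASD` / `NON_ASD`.
#' @return One-row tibble `tp`, `fp`, `tn`, `fn`, `n`.
#' @examples
#' df <- tibble::tibble(label = c("ASD", "ASD", "NON_ASD"),
#'                      pred = c("ASD", "NON_ASD", "NON_ASD"))
#' confusion(df)
#' @export
confusion <- function(data, truth = label, estimate = pred) {
  truth_v <- as_class_factor(dplyr::pull(data, {{ truth }}))
  est_v <- as_class_factor(dplyr::pull(data, {{ estimate }}))
  bad <- is.na(truth_v) | is.na(est_v)
  if (any(bad)) {
    abort(paste0("predictions do not cover all labelled subjects; missing for: ",
                 offending_ids(data, bad)))
  }
  tibble::tibble(
    tp = sum(truth_v == "ASD" & est_v == "ASD"),
    fp = sum(truth_v == "NON_ASD" & est_v == "ASD"),
    tn = sum(truth_v == "NON_ASD" & est_v == "NON_ASD"),
    fn = sum(truth_v == "ASD" & est_v == "NON_ASD"),
    n = length(truth_v)
  )
}

#' Diagnostic performance of a continuous score
#'
#' Thresholds a score in `[0, 1]` (class call = ASD iff `score >= threshold`)
#' and reports the standard diagnostic-accuracy panel: rank-based AUC of the
#' score (tie-aware, threshold-free), accuracy, sensitivity `tp/(tp+fn)`,
#' specificity `tn/(tn+fp)` and Youden's J = sensitivity + specificity - 1.
#'
#' @param data Data frame with one row per subject.
#' @param truth,score Columns (tidy-eval) holding the true label
#'   (`ASD`/`NON_ASD`) and the score (e.g., a forest's ASD vote fraction).
#' @param threshold Classification threshold on the score (default 0.5).
#' @return One-row tibble `auc`, `acc`, `sensitivity`, `specificity`,
#'   `youden_j`, `n`.
#' @examples
#' df <- tibble::tibble(label = rep(c("ASD", "NON_ASD"), each = 3),
#'                      score = c(.9, .8, .4, .6, .2, .1))
#' performance(df)
#' @export
performance <- function(data, truth = label, score = score, threshold = 0.5) {
  truth_v <- as_class_factor(dplyr::pull(data, {{ truth }}))
  score_v <- dplyr::pull(data, {{ score }})
  bad <- is.na(truth_v) | is.na(score_v)
  if (any(bad)) {
    abort(paste0("scores do not cover all labelled subjects; missing for: ",
                 offending_ids(data, bad)))
  }
  if (length(unique(truth_v)) < 2) {
    abort("performance is undefined on one-class input (AUC needs both classes)")
  }
  cc <- confusion(
    tibble::tibble(label = truth_v,
                   pred = ifelse(score_v >= threshold, "ASD", "NON_ASD"))
  )
  sens <- cc$tp / (cc$tp + cc$fn)
  spec <- cc$tn / (cc$tn + cc$fp)
  tibble::tibble(
    auc = rank_auc(score_v, truth_v == "ASD"),
    acc = (cc$tp + cc$tn) / cc$n,
    sensitivity = sens,
    specificity = spec,
    youden_j = sens + spec - 1,
    n = cc$n
  )
}

#' McNemar comparison of two paired classifiers
#'
#' Compares the per-subject correctness of two prediction vectors on the
#' same subjects through the discordant counts `b` (A correct, B wrong) and
#' `c` (A wrong, B correct). Methods: `chi2` uses `(b - c)^2 / (b + c)`,
#' `chi2_corrected` the continuity-corrected `(|b - c| - 1)^2 / (b + c)`
#' (clamped at zero when `b = c`)
#' (both against a 1-df chi-square); `exact` uses the two-sided binomial
#' test of `b` successes in `b + c` trials at p = 1/2 (its `statistic` is
#' `min(b, c)`). The default `auto` follows small-sample practice: the
#' corrected statistic when `min(b, c) < 25`, plain `chi2` otherwise. With
#' no discordant pairs the statistic is 0 and p = 1.
#'
#' @param data Data frame with one row per subject.
#' @param truth,pred_a,pred_b Columns (tidy-eval): true label and the two
#'   classifiers' calls, all coded `ASD` / `NON_ASD`.
#' @param method `"auto"`, `"chi2"`, `"chi2_corrected"` or `"exact"`.
#' @return One-row tibble `b`, `c`, `statistic`, `p_value`, `method`, `n`.
#' @examples
#' df <- tibble::tibble(label = rep("ASD", 4),
#'                      m_full = c("ASD", "ASD", "NON_ASD", "ASD"),
#'                      m_small = c("ASD", "NON_ASD", "ASD", "ASD"))
#' mcnemar_compare(df, pred_a = m_full, pred_b = m_small, method = "exact")
#' @export
mcnemar_compare <- function(data, truth = label, pred_a = pred_a, pred_b = pred_b,
                            method = c("auto", "chi2", "chi2_corrected", "exact")) {
  method <- match.arg(method)
  truth_v <- as_class_factor(dplyr::pull(data, {{ truth }}))
  a_v <- as_class_factor(dplyr::pull(data, {{ pred_a }}))
  b_v <- as_class_factor(dplyr::pull(data, {{ pred_b }}))
  bad <- is.na(truth_v) | is.na(a_v) | is.na(b_v)
  if (any(bad)) {
    abort(paste0("both prediction vectors must cover all labelled subjects; missing for: ",
                 offending_ids(data, bad)))
  }
  a_ok <- a_v == truth_v
  b_ok <- b_v == truth_v
  b_cnt <- sum(a_ok & !b_ok)
  c_cnt <- sum(!a_ok & b_ok)
  if (method == "auto") {
    method <- if (min(b_cnt, c_cnt) < 25) "chi2_corrected" else "chi2"
  }
  nd <- b_cnt + c_cnt
  if (nd == 0) {
    stat <- 0
    p <- 1
  } else if (method == "chi2") {
    stat <- (b_cnt - c_cnt)^2 / nd
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
  } else if (method == "chi2_corrected") {
    # correction clamped at 0 so it can never exceed the uncorrected statistic
    stat <- max(abs(b_cnt - c_cnt) - 1, 0)^2 / nd
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
  } else {
    stat <- min(b_cnt, c_cnt)
    p <- min(1, 2 * pbinom(min(b_cnt, c_cnt), nd, 0.5))
  }
  tibble::tibble(b = b_cnt, c = c_cnt, statistic = stat, p_value = p,
                 method = method, n = length(truth_v))
}
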