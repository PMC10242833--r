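#' Class-conditional code probabilities of a proportional-odds item
#'
#' Each synthetic item follows an ordered-logit (proportional-odds) model.
#' The non-ASD group draws codes from the baseline distribution with
#' location 0; the ASD group from the same cutpoints with its location
#' shifted by `shift`, which moves probability mass toward higher codes.
#' Baseline cutpoints are chosen so that the non-ASD distribution is uniform
#' over the codes `0 .. n_levels - 1`.
#'
#' @param n_levels Number of ordinal codes (codes are `0 .. n_levels - 1`).
#' @param shift Non-negative location shift applied to the ASD group;
#'   0 makes the item non-informative.
#' @return A tibble with columns `code`, `p_nonasd`, `p_asd`. Both
#'   probability columns sum to 1 exactly.
#' @examples
#' ordinal_item_probs(3, shift = 1.5)
#' @export
ordinal_item_probs <- function(n_levels, shift) {
  if (!is.numeric(n_levels) || length(n_levels) != 1 || n_levels < 2) {
    abort("`n_levels` must be a single integer >= 2")
  }
  if (!is.numeric(shift) || length(shift) != 1 || !is.finite(shift) || shift < 0) {
    abort("`shift` must be a single finite number >= 0")
  }
  cuts <- qlogis(seq_len(n_levels - 1) / n_levels)
  tibble::tibble(
    code = 0:(n_levels - 1),
    p_nonasd = diff(c(0, plogis(cuts), 1)),
    p_asd = diff(c(0, plogis(cuts - shift), 1))
  )
}

#' Exact single-item AUC implied by a proportional-odds shift
#'
#' Closed-form probability that a randomly drawn ASD code exceeds a randomly
#' drawn non-ASD code, counting ties as one half — the population value that
#' [single_item_discriminability()] estimates from a finite cohort.
#'
#' @inheritParams ordinal_item_probs
#' @return A single number in `[0.5, 1)` (0.5 when `shift = 0`).
#' @examples
#' ordinal_item_auc(3, shift = 0)    # 0.5
#' ordinal_item_auc(3, shift = 2)    # about 0.74
#' @export
ordinal_item_auc <- function(n_levels, shift) {
  p <- ordinal_item_probs(n_levels, shift)
  cum_non <- cumsum(p$p_nonasd)                 # P(non-ASD code <= c)
  below <- c(0, head(cum_non, -1))              # P(non-ASD code <  c)
  sum(p$p_asd * below) + 0.5 * sum(p$p_asd * p$p_nonasd)
}
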