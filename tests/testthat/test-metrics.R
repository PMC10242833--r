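test_that("confusion counts match hand tallies and symmetry", {
  df <- tibble::tibble(label = rep(c("ASD", "NON_ASD"), each = 10), pred = label)
  expect_equal(confusion(df), tibble::tibble(tp = 10L, fp = 0L, tn = 10L, fn = 0L, n = 20L))

  inverted <- dplyr::mutate(df, pred = ifelse(label == "ASD", "NON_ASD", "ASD"))
  expect_equal(confusion(inverted),
               tibble::tibble(tp = 0L, fp = 10L, tn = 0L, fn = 10L, n = 20L))

  df3 <- tibble::tibble(label = c("ASD", "ASD", "ASD", "NON_ASD", "NON_ASD"),
                        pred = c("ASD", "ASD", "NON_ASD", "NON_ASD", "ASD"))
  expect_equal(confusion(df3), tibble::tibble(tp = 2L, fp = 1L, tn = 1L, fn = 1L, n = 5L))
})

test_that("confusion reports offending subjects on coverage mismatch", {
  df <- tibble::tibble(subject_id = c("a", "b", "c"),
                       label = c("ASD", "ASD", "NON_ASD"),
                       pred = c("ASD", NA, "NON_ASD"))
  expect_error(confusion(df), "\\bb\\b")
  expect_error(confusion(tibble::tibble(label = "ASD", pred = "maybe")), "class labels")
})

test_that("performance agrees with direct ratios and its Youden invariant", {
  # 83/17 and 80/20 split: sens 0.83, spec 0.80, J 0.63
  df <- tibble::tibble(
    label = rep(c("ASD", "NON_ASD"), c(100, 100)),
    score = c(rep(1, 83), rep(0, 17), rep(0, 80), rep(1, 20))
  )
  perf <- performance(df)
  expect_equal(perf$sensitivity, 0.83)
  expect_equal(perf$specificity, 0.80)
  expect_equal(perf$youden_j, 0.63)
  expect_equal(perf$acc, (83 + 80) / 200)
  expect_equal(perf$youden_j, perf$sensitivity + perf$specificity - 1)
})

test_that("perfect separation gives AUC and accuracy 1 at a separating threshold", {
  df <- tibble::tibble(label = rep(c("ASD", "NON_ASD"), each = 4),
                       score = c(.9, .8, .75, .7, .3, .2, .2, .1))
  perf <- performance(df, threshold = 0.5)
  expect_equal(perf$auc, 1)
  expect_equal(perf$acc, 1)
  expect_error(performance(df[1:4, ]), "one-class")
})

test_that("AUC equals the hand-enumerated concordant-pair fraction and pROC on random data", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      n1 <- sample(2:6, 1)
      n0 <- sample(2:6, 1)
      scores <- round(runif(n1 + n0), 1)  # rounding forces ties
      df <- tibble::tibble(label = rep(c("ASD", "NON_ASD"), c(n1, n0)), score = scores)
      got <- performance(df)$auc
      expect_equal(got, pair_auc(scores[1:n1], scores[(n1 + 1):(n1 + n0)]))
    }
  })
  skip_if_not_installed("pROC")
  withr::with_seed(1, {
    df <- tibble::tibble(label = sample(rep(c("ASD", "NON_ASD"), 25)),
                         score = round(runif(50), 1))
    roc <- pROC::roc(response = df$label, predictor = df$score,
                     levels = c("NON_ASD", "ASD"), direction = "<", quiet = TRUE)
    expect_equal(performance(df)$auc, as.numeric(pROC::auc(roc)))
  })
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(3, {
    df <- tibble::tibble(label = rep(c("ASD", "NON_ASD"), c(12, 15)),
                         score = runif(27))
    base <- performance(df)$auc
    for (f in list(\(x) x^3, \(x) plogis(5 * x - 2), \(x) rank(x) / 28)) {
      df2 <- dplyr::mutate(df, score = f(score))
      expect_equal(performance(df2)$auc, base)
    }
  })
})

test_that("threshold extremes pin sensitivity and specificity", {
  withr::with_seed(8, {
    df <- tibble::tibble(label = rep(c("ASD", "NON_ASD"), c(9, 11)),
                         score = runif(20))
  })
  expect_equal(performance(df, threshold = 0)$sensitivity, 1)
  expect_equal(performance(df, threshold = 1 + 1e-9)$specificity, 1)
})

test_that("McNemar closed forms match their hand values", {
  mk <- function(b, c) {
    # construct predictions realizing discordant counts (b, c) on ASD subjects
    n <- b + c + 4
    tibble::tibble(
      label = rep("ASD", n),
      pred_a = c(rep("ASD", b), rep("NON_ASD", c), rep("ASD", 2), rep("NON_ASD", 2)),
      pred_b = c(rep("NON_ASD", b), rep("ASD", c), rep("ASD", 2), rep("NON_ASD", 2))
    )
  }
  r <- mcnemar_compare(mk(5, 5), method = "chi2")
  expect_equal(r$b, 5)
  expect_equal(r$c, 5)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  r <- mcnemar_compare(mk(10, 2), method = "chi2_corrected")
  expect_equal(r$statistic, 49 / 12)
  expect_equal(r$p_value, pchisq(49 / 12, 1, lower.tail = FALSE))

  r <- mcnemar_compare(mk(3, 0), method = "exact")
  expect_equal(r$p_value, 0.25)

  r <- mcnemar_compare(mk(0, 0), method = "exact")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # auto: corrected below 25 discordant on the smaller side, plain chi2 above
  expect_equal(mcnemar_compare(mk(10, 2))$method, "chi2_corrected")
  expect_equal(mcnemar_compare(mk(30, 26))$method, "chi2")
})

test_that("McNemar discordant counts match brute force over all paired vectors on few subjects", {
  # exhaustive: 4 subjects, all 2^4 x 2^4 prediction pairs against fixed labels
  labels <- c("ASD", "ASD", "NON_ASD", "NON_ASD")
  calls <- expand.grid(rep(list(c("ASD", "NON_ASD")), 4), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(calls))) {
    for (j in seq_len(nrow(calls))) {
      a <- unlist(calls[i, ], use.names = FALSE)
      b <- unlist(calls[j, ], use.names = FALSE)
      got <- mcnemar_compare(tibble::tibble(label = labels, pred_a = a, pred_b = b),
                             method = "chi2")
      b_ref <- sum(a == labels & b != labels)
      c_ref <- sum(a != labels & b == labels)
      expect_equal(got$b, b_ref)
      expect_equal(got$c, c_ref)
      if (b_ref + c_ref > 0) {
        expect_equal(got$statistic, (b_ref - c_ref)^2 / (b_ref + c_ref))
      } else {
        expect_equal(got$statistic, 0)
      }
    }
  }
})

test_that("McNemar agrees with stats::mcnemar.test and binom.test oracles", {
  cases <- list(c(10, 2), c(7, 7), c(1, 12), c(25, 30), c(0, 4))
  for (bc in cases) {
    n <- sum(bc) + 2
    df <- tibble::tibble(
      label = rep("ASD", n),
      pred_a = c(rep("ASD", bc[1]), rep("NON_ASD", bc[2]), "ASD", "NON_ASD"),
      pred_b = c(rep("NON_ASD", bc[1]), rep("ASD", bc[2]), "ASD", "NON_ASD")
    )
    tab <- matrix(c(1, bc[2], bc[1], 1), 2)  # concordant cells arbitrary
    ref_corr <- stats::mcnemar.test(tab, correct = TRUE)
    ref_plain <- stats::mcnemar.test(tab, correct = FALSE)
    got_corr <- mcnemar_compare(df, method = "chi2_corrected")
    got_plain <- mcnemar_compare(df, method = "chi2")
    expect_equal(got_corr$statistic, unname(ref_corr$statistic))
    expect_equal(got_corr$p_value, ref_corr$p.value)
    expect_equal(got_plain$statistic, unname(ref_plain$statistic))
    expect_equal(got_plain$p_value, ref_plain$p.value)
    ref_exact <- stats::binom.test(bc[1], sum(bc), 0.5)
    expect_equal(mcnemar_compare(df, method = "exact")$p_value, ref_exact$p.value)
  }
})
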