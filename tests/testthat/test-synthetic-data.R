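test_that("ordered-logit class-conditional distributions are proper and shift mass upward", {
  for (L in c(2, 3, 5)) {
    for (s in c(0, 0.5, 1.5, 3)) {
      p <- ordinal_item_probs(L, s)
      expect_equal(sum(p$p_nonasd), 1)
      expect_equal(sum(p$p_asd), 1)
      expect_true(all(p$p_asd > 0) && all(p$p_nonasd > 0))
    }
    expect_equal(ordinal_item_probs(L, 0)$p_asd, ordinal_item_probs(L, 0)$p_nonasd)
  }
  # larger shift => stochastically larger codes => larger exact AUC
  aucs <- vapply(seq(0, 4, by = 0.5), \(s) ordinal_item_auc(3, s), numeric(1))
  expect_equal(aucs[1], 0.5)
  expect_true(all(diff(aucs) > 0))
})

test_that("cohort generation is deterministic and respects the spec", {
  spec <- small_spec(seed = 7)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)

  expect_equal(nrow(a), 120)
  expect_equal(sum(a$label == "ASD"), 60)
  meta <- cohort_items(a)
  expect_identical(meta$item_id, spec$items$item_id)
  for (i in seq_len(nrow(meta))) {
    codes <- a[[meta$item_id[i]]]
    expect_true(all(codes >= 0 & codes < meta$n_levels[i]))
  }
  # a different seed gives different draws
  expect_false(identical(generate_cohort(small_spec(seed = 8)), a))
})

test_that("cohort spec validation names the offending field", {
  items <- instrument_items(2, 2)
  expect_error(cohort_spec(0, 10, items), "n_asd")
  expect_error(cohort_spec(10, -1, items), "n_nonasd")
  expect_error(cohort_spec(10, 10, items, adi_missing_fraction = 1.2), "adi_missing_fraction")
  expect_error(cohort_spec(10, 10, items[0, ]), "items")
  bad <- items
  bad$item_id[2] <- bad$item_id[1]
  expect_error(cohort_spec(10, 10, bad), "item_id")
  bad <- items
  bad$n_levels <- 1L
  expect_error(cohort_spec(10, 10, bad), "n_levels")
  bad <- items
  bad$shift[1] <- -0.5
  expect_error(cohort_spec(10, 10, bad), "shift")
})

test_that("with zero shift the two groups draw from the same distribution", {
  spec <- cohort_spec(1500, 1500,
                      items = instrument_items(2, 0, n_levels = 4), seed = 11)
  co <- generate_cohort(spec)
  for (id in c("ados_01", "ados_02")) {
    tab <- table(co$label, co[[id]])
    freq_asd <- tab["ASD", ] / sum(tab["ASD", ])
    freq_non <- tab["NON_ASD", ] / sum(tab["NON_ASD", ])
    expect_true(max(abs(freq_asd - freq_non)) < 0.05)
    auc <- single_item_discriminability(co, id)
    expect_true(abs(auc - 0.5) < 0.03)
  }
})

test_that("a shifted item reaches its closed-form discriminability", {
  # exact AUC for n_levels = 3, shift = 2 from the ordered-logit construction
  exact <- ordinal_item_auc(3, 2)
  expect_gt(exact, 0.70)
  spec <- cohort_spec(2000, 2000,
                      items = tibble::tibble(item_id = "it1", instrument = "ADOS",
                                             n_levels = 3L, shift = 2),
                      seed = 3)
  co <- generate_cohort(spec)
  emp <- single_item_discriminability(co, "it1")
  expect_gt(emp, 0.70)
  expect_true(abs(emp - exact) < 0.02)
})

test_that("empirical discriminability is monotone in the shift", {
  shifts <- c(0, 0.75, 1.5, 3)
  aucs <- vapply(seq_along(shifts), function(i) {
    spec <- cohort_spec(1200, 1200,
                        items = tibble::tibble(item_id = "x", instrument = "ADOS",
                                               n_levels = 3L, shift = shifts[i]),
                        seed = 20)
    single_item_discriminability(generate_cohort(spec), "x")
  }, numeric(1))
  # exact AUC gaps are >= 0.08 between neighbours; Monte-Carlo noise ~0.01
  expect_true(all(diff(aucs) > 0))
})

test_that("ADI-R missingness is block-wise, all-or-none, and never touches ADOS items", {
  spec <- small_spec(seed = 5, adi_missing_fraction = 0.4)
  co <- generate_cohort(spec)
  meta <- cohort_items(co)
  ados <- meta$item_id[meta$instrument == "ADOS"]
  adir <- meta$item_id[meta$instrument == "ADI_R"]
  expect_false(anyNA(co[ados]))
  miss <- is.na(as.matrix(co[adir]))
  per_subject <- rowSums(miss)
  expect_true(all(per_subject %in% c(0, length(adir))))
  expect_gt(sum(per_subject > 0), 0)
  # complete-case filter drops exactly the missing-block subjects
  kept <- filter_complete_cases(co)
  expect_equal(nrow(kept), sum(per_subject == 0))
  expect_equal(nrow(filter_complete_cases(co, features = ados)), nrow(co))
})

test_that("cohorts round-trip through the TSV/JSON writer and reader", {
  co <- generate_cohort(small_spec(seed = 9, adi_missing_fraction = 0.3))
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  back <- read_cohort(paths$matrix, paths$items, paths$labels)
  expect_equal(as.data.frame(back[names(co)]), as.data.frame(co))
  expect_equal(cohort_items(back)$item_id, cohort_items(co)$item_id)
  # comma-separated variant is accepted too
  csv <- file.path(dir, "labels.csv")
  labs <- read.delim(paths$labels)
  write.csv(labs, csv, row.names = FALSE, quote = FALSE)
  back2 <- read_cohort(paths$matrix, paths$items, csv)
  expect_equal(back2$label, back$label)
})

test_that("single-item discriminability matches hand enumeration and handles degenerate input", {
  df <- tibble::tibble(label = c("ASD", "ASD", "NON_ASD", "NON_ASD"),
                       it = c(2L, 2L, 0L, 0L))
  attr(df, "item_meta") <- tibble::tibble(item_id = "it", instrument = "ADOS",
                                          n_levels = 3L, shift = 0)
  expect_equal(single_item_discriminability(df, "it"), 1)

  df$it <- c(1L, 0L, 1L, 0L)  # identical multisets in both groups
  expect_equal(single_item_discriminability(df, "it"), 0.5)

  # ASD {0,1,2} vs non-ASD {0,0,1}: 9 pairs, hand count = (5 + 3/2)/9
  df2 <- tibble::tibble(label = rep(c("ASD", "NON_ASD"), each = 3),
                        it = c(0L, 1L, 2L, 0L, 0L, 1L))
  expect_equal(single_item_discriminability(df2, "it"), 6.5 / 9)
  expect_equal(single_item_discriminability(df2, "it"),
               pair_auc(c(0, 1, 2), c(0, 0, 1)))

  df2$it[4:6] <- NA_integer_
  expect_error(single_item_discriminability(df2, "it"), "missing")
  expect_error(single_item_discriminability(df2, "nope"), "not present")
})

test_that("item_discriminability separates informative from null items at scale", {
  co <- generate_cohort(default_cohort_spec(seed = 2))
  disc <- item_discriminability(co)
  meta <- cohort_items(co)
  informative <- meta$item_id[meta$shift > 0]
  null_items <- setdiff(meta$item_id, informative)
  expect_true(all(disc$auc[disc$item_id %in% informative] > 0.6))
  expect_true(all(abs(disc$auc[disc$item_id %in% null_items] - 0.5) < 0.12))
})
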