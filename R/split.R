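#' Development/validation split with cross-validation folds
#'
#' Splits a cohort, stratified by class, into a development portion and a
#' held-out validation portion (default 25%), and partitions the
#' development subjects into `n_folds` stratified cross-validation folds,
#' each fold serving once as the test set (about 5% of development when
#' `n_folds = 20`). The validation subjects never appear in any fold, so
#' importance ranking and model training cannot see them.
#'
#' @param data Cohort tibble with `subject_id` and `label` columns.
#' @param seed Integer seed; the plan is deterministic given it.
#' @param validation_fraction Held-out fraction per class (default 0.25).
#' @param n_folds Number of folds over the development portion (default 20).
#' @param scheme `"partition"` (each development subject tested exactly
#'   once) or `"resample"` (`n_folds` independent stratified splits holding
#'   out `1/n_folds` of development each time).
#' @return An object of class `split_plan` with `development_ids`,
#'   `validation_ids` and `folds` (a list of `train_ids`/`test_ids` pairs).
#' @export
make_split <- function(data, seed, validation_fraction = 0.25, n_folds = 20,
                       scheme = c("partition", "resample")) {
  scheme <- match.arg(scheme)
  lab <- as_class_factor(data$label)
  ids <- data$subject_id
  counts <- table(lab)
  if (any(counts < 2) || length(counts) < 2) {
    abort("class too small to stratify: need at least 2 subjects per class")
  }
  withr::with_seed(as.integer(seed), {
    val_ids <- character(0)
    for (cl in .classes) {
      cl_ids <- ids[lab == cl]
      n_val <- round(validation_fraction * length(cl_ids))
      n_val <- min(max(n_val, 1L), length(cl_ids) - 1L)
      val_ids <- c(val_ids, sample(cl_ids, n_val))
    }
    dev_ids <- setdiff(ids, val_ids)
    dev_lab <- lab[match(dev_ids, ids)]
    folds <- if (scheme == "partition") {
      # stratified partition; per-class remainders go to the currently
      # smallest folds so fold totals differ by at most one subject
      fold_of <- integer(length(dev_ids))
      fold_sizes <- integer(n_folds)
      for (cl in .classes) {
        idx <- which(dev_lab == cl)
        n_c <- length(idx)
        counts <- rep(n_c %/% n_folds, n_folds)
        r <- n_c %% n_folds
        if (r > 0) {
          extra <- order(fold_sizes + runif(n_folds))[seq_len(r)]
          counts[extra] <- counts[extra] + 1
        }
        fold_of[idx] <- sample(rep.int(seq_len(n_folds), counts))
        fold_sizes <- fold_sizes + counts
      }
      lapply(seq_len(n_folds), function(f) {
        list(train_ids = dev_ids[fold_of != f], test_ids = dev_ids[fold_of == f])
      })
    } else {
      lapply(seq_len(n_folds), function(f) {
        test <- character(0)
        for (cl in .classes) {
          cl_ids <- dev_ids[dev_lab == cl]
          n_test <- max(1L, round(length(cl_ids) / n_folds))
          test <- c(test, sample(cl_ids, n_test))
        }
        list(train_ids = setdiff(dev_ids, test), test_ids = test)
      })
    }
  })
  structure(
    list(development_ids = dev_ids, validation_ids = val_ids, folds = folds,
         seed = as.integer(seed), n_folds = as.integer(n_folds), scheme = scheme),
    class = "split_plan"
  )
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d development + %d validation subjects, %d %s folds, seed %d\n",
              length(x$development_ids), length(x$validation_ids),
              x$n_folds, x$scheme, x$seed))
  invisible(x)
}
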