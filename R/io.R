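#' Write a cohort to plain-text files
#'
#' Persists a cohort as three files in `dir`: `matrix.tsv` (first column
#' `subject_id`, one column per item, missing codes as `NA`), `items.json`
#' (item metadata sidecar) and `labels.tsv` (`subject_id`, `label`).
#'
#' @param data A cohort tibble from [generate_cohort()] or [read_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named list of the three file paths.
#' @export
write_cohort <- function(data, dir) {
  meta <- cohort_items(data)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(
    matrix = file.path(dir, "matrix.tsv"),
    items = file.path(dir, "items.json"),
    labels = file.path(dir, "labels.tsv")
  )
  mat <- data[c("subject_id", meta$item_id)]
  write.table(mat, paths$matrix, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(meta, paths$items, dataframe = "rows", digits = NA)
  write.table(data.frame(subject_id = data$subject_id, label = as.character(data$label)),
              paths$labels, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

# sniff a header line for its delimiter (tab or comma); header is mandatory
detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0) abort(paste0(path, ": empty file (header row is mandatory)"))
  if (grepl("\t", first)) "\t" else ","
}

read_table_auto <- function(path) {
  df <- read.delim(path, sep = detect_sep(path), header = TRUE,
                   check.names = FALSE, stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}

#' Read a cohort from delimited files
#'
#' Inverse of [write_cohort()]. The matrix and label files may be tab- or
#' comma-separated (detected from the header line); a header row is
#' mandatory. Codes outside an item's declared range raise an error.
#'
#' @param matrix_file Subjects-by-items code table; first column must be
#'   `subject_id`.
#' @param items_file JSON item-metadata sidecar with at least `item_id` and
#'   `instrument` per item.
#' @param labels_file Two-column table `subject_id`, `label` with labels
#'   `ASD` / `NON_ASD`.
#' @return A cohort tibble as produced by [generate_cohort()].
#' @export
read_cohort <- function(matrix_file, items_file, labels_file) {
  mat <- read_table_auto(matrix_file)
  if (names(mat)[1] != "subject_id") {
    abort(paste0(matrix_file, ": first column must be named subject_id"))
  }
  meta <- tibble::as_tibble(jsonlite::fromJSON(items_file))
  if (!all(c("item_id", "instrument") %in% names(meta))) {
    abort(paste0(items_file, ": item metadata must contain item_id and instrument"))
  }
  labs <- read_table_auto(labels_file)
  if (!all(c("subject_id", "label") %in% names(labs))) {
    abort(paste0(labels_file, ": label file must contain subject_id and label"))
  }
  missing_items <- setdiff(meta$item_id, names(mat))
  if (length(missing_items) > 0) {
    abort(paste0(matrix_file, ": missing item column(s): ",
                 paste(missing_items, collapse = ", ")))
  }
  extra <- setdiff(labs$subject_id, mat$subject_id)
  absent <- setdiff(mat$subject_id, labs$subject_id)
  if (length(extra) > 0 || length(absent) > 0) {
    abort(paste0("subject ids differ between matrix and labels; e.g. ",
                 paste(head(c(extra, absent), 5), collapse = ", ")))
  }
  out <- dplyr::inner_join(labs["subject_id"] |> dplyr::mutate(label = as_class_factor(labs$label)),
                           mat, by = "subject_id")
  for (i in seq_len(nrow(meta))) {
    id <- meta$item_id[i]
    out[[id]] <- as.integer(out[[id]])
    if ("n_levels" %in% names(meta)) {
      ok <- is.na(out[[id]]) | (out[[id]] >= 0 & out[[id]] < meta$n_levels[i])
      if (!all(ok)) {
        abort(paste0(matrix_file, ": item ", id, " has codes outside 0..",
                     meta$n_levels[i] - 1))
      }
    }
  }
  out <- tibble::as_tibble(out[c("subject_id", "label", meta$item_id)])
  attr(out, "item_meta") <- meta
  out
}
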