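log_levels <- c(DEBUG = 10, INFO = 20, WARN = 30, QUIET = 40)

log_msg <- function(config, level, fmt, ...) {
  if (log_levels[[level]] >= log_levels[[config$log_level]]) {
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
  }
  invisible(NULL)
}

#' Configure an end-to-end analysis run
#'
#' A run takes its cohort either from a synthetic [cohort_spec()] or from
#' files on disk (exactly one of the two), restricts it to a feature
#' universe (`"combined"` = ADOS + ADI-R, `"ados_only"`), applies the
#' complete-case policy, splits, runs [select_models()] and persists the
#' reports.
#'
#' @param spec Optional [cohort_spec()] for a synthetic cohort.
#' @param matrix_file,items_file,labels_file Optional input files for a
#'   real cohort (see [read_cohort()]).
#' @param universe `"combined"` or `"ados_only"`.
#' @param selection A [selection_config()].
#' @param out_dir Output directory for reports (created if needed); `NULL`
#'   to keep results in memory only.
#' @param seed Integer seed driving the split and all forest fits.
#' @param ks Optional subset of feature counts to evaluate (see
#'   [select_models()]).
#' @param log_level `"DEBUG"`, `"INFO"`, `"WARN"` or `"QUIET"`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(spec = NULL, matrix_file = NULL, items_file = NULL,
                       labels_file = NULL, universe = c("combined", "ados_only"),
                       selection = selection_config(), out_dir = NULL,
                       seed = 1L, ks = NULL,
                       log_level = c("INFO", "DEBUG", "WARN", "QUIET")) {
  universe <- match.arg(universe)
  log_level <- match.arg(log_level)
  has_files <- !is.null(matrix_file) || !is.null(items_file) || !is.null(labels_file)
  if (is.null(spec) == !has_files) {
    abort("provide exactly one cohort source: `spec` or the three input files")
  }
  if (has_files && (is.null(matrix_file) || is.null(items_file) || is.null(labels_file))) {
    abort("file input needs all of `matrix_file`, `items_file`, `labels_file`")
  }
  structure(
    list(spec = spec, matrix_file = matrix_file, items_file = items_file,
         labels_file = labels_file, universe = universe, selection = selection,
         out_dir = out_dir, seed = as.integer(seed), ks = ks,
         log_level = log_level),
    class = "run_config"
  )
}

load_cohort <- function(config) {
  if (!is.null(config$spec)) {
    generate_cohort(config$spec)
  } else {
    read_cohort(config$matrix_file, config$items_file, config$labels_file)
  }
}

config_hash <- function(config) {
  stripped <- config[setdiff(names(config), c("out_dir", "log_level"))]
  rlang::hash(stripped)
}

write_csv_commented <- function(df, path, hash) {
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  write.table(df, con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a report CSV written by [run_pipeline()]
#'
#' @param path CSV path (first line is a `# config_hash:` comment).
#' @return A tibble.
#' @export
read_report_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, comment.char = "#", check.names = FALSE))
}

metrics_table <- function(report) {
  ev <- report$evaluations
  rows <- tibble::tibble(
    model = c("full", "optimal", "minimal"),
    k = c(report$n_features, report$optimal_k, report$minimal_k)
  )
  rows <- rows[!is.na(rows$k), , drop = FALSE]
  dplyr::inner_join(rows, ev, by = "k")
}

ranked_items_table <- function(report, meta) {
  dplyr::left_join(report$ranking,
                   dplyr::select(meta, "item_id", "instrument"),
                   by = "item_id")
}

serialize_report <- function(report) {
  list(
    seed = report$seed,
    n_features = report$n_features,
    optimal_k = report$optimal_k,
    minimal_k = report$minimal_k,
    ranking = as.data.frame(report$ranking),
    evaluations = as.data.frame(report$evaluations),
    config = list(
      w1 = report$config$w1, w2 = report$config$w2, alpha = report$config$alpha,
      complexity_normalization = report$config$complexity_normalization,
      threshold = report$config$threshold,
      mcnemar_method = report$config$mcnemar_method,
      cv_scheme = report$config$cv_scheme,
      rf = unclass(report$config$rf)
    )
  )
}

#' Write a selection report to JSON
#'
#' Deterministic serialization of a [select_models()] report (ranking,
#' per-k metrics, optimal/minimal models, configuration echo): identical
#' reports produce byte-identical files.
#'
#' @param report A `selection_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_selection_report <- function(report, path) {
  jsonlite::write_json(serialize_report(report), path,
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       na = "null")
  invisible(path)
}

write_run_outputs <- function(report, meta, manifest, out_dir, hash) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- list(
    report = file.path(out_dir, "report.json"),
    metrics = file.path(out_dir, "metrics_table.csv"),
    ranking = file.path(out_dir, "ranked_items.csv"),
    curve = file.path(out_dir, "auc_curve.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_selection_report(report, paths$report)
  write_csv_commented(metrics_table(report), paths$metrics, hash)
  write_csv_commented(ranked_items_table(report, meta), paths$ranking, hash)
  write_csv_commented(
    dplyr::select(report$evaluations, "k", "test_auc", "val_auc", "weighted_score"),
    paths$curve, hash
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA)
  paths
}

#' Run one full analysis
#'
#' Executes the whole pipeline for one feature universe: generate or load
#' the cohort, drop incomplete cases over the universe, build the
#' development/validation split, run [select_models()], and (when
#' `out_dir` is set) persist `report.json`, a metrics table
#' (full/optimal/minimal rows), the ranked item list, the AUC-versus-k
#' curve and a run manifest recording the config hash, seed, package
#' version and subject counts before/after filtering. The run seed drives
#' the split and every forest fit, so a rerun with the same configuration
#' reproduces all outputs byte-identically.
#'
#' @param config A [run_config()].
#' @return An object of class `pipeline_run`: the `selection_report`, the
#'   manifest, and output paths (if written).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  cohort <- load_cohort(config)
  log_msg(config, "INFO", "cohort loaded: %d subjects, %d items",
          nrow(cohort), nrow(cohort_items(cohort)))
  features <- feature_universe(cohort, config$universe)
  filtered <- filter_complete_cases(cohort, features)
  n_before <- nrow(cohort)
  n_after <- nrow(filtered)
  log_msg(config, "INFO", "universe %s: %d features; complete cases %d/%d (%d dropped)",
          config$universe, length(features), n_after, n_before, n_before - n_after)
  sel <- config$selection
  sel$rf$seed <- config$seed
  plan <- make_split(filtered, config$seed, scheme = sel$cv_scheme)
  log_msg(config, "INFO", "split: %d development / %d validation subjects",
          length(plan$development_ids), length(plan$validation_ids))
  report <- select_models(filtered, plan, sel, features, ks = config$ks)
  for (i in seq_len(nrow(report$evaluations))) {
    log_msg(config, "DEBUG", "k = %d: val AUC %.3f, weighted score %.3f",
            report$evaluations$k[i], report$evaluations$val_auc[i],
            report$evaluations$weighted_score[i])
  }
  log_msg(config, "INFO", "selection done in %.1f s: optimal k = %d, minimal k = %s",
          as.numeric(difftime(Sys.time(), t0, units = "secs")),
          report$optimal_k, as.character(report$minimal_k))
  hash <- config_hash(config)
  manifest <- list(
    config_hash = hash,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("itemforest")),
    universe = config$universe,
    n_features = length(features),
    n_subjects = n_before,
    n_complete = n_after,
    n_dropped = n_before - n_after,
    n_development = length(plan$development_ids),
    n_validation = length(plan$validation_ids),
    class_counts = as.list(table(as.character(filtered$label)))
  )
  paths <- if (!is.null(config$out_dir)) {
    write_run_outputs(report, cohort_items(cohort), manifest, config$out_dir, hash)
  } else {
    NULL
  }
  structure(list(report = report, manifest = manifest, paths = paths,
                 config = config),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> universe %s, seed %d\n", x$config$universe, x$config$seed))
  print(x$report)
  invisible(x)
}

#' Compare the combined and ADOS-only feature universes
#'
#' Runs the selection procedure for both universes on the *same* subjects
#' (complete cases over the combined universe) and the *same*
#' development/validation split, so the comparison is paired, and tests the
#' two full-feature models' validation predictions against each other with
#' McNemar's test.
#'
#' @param config A [run_config()]; its `universe` field is ignored.
#' @return An object of class `universe_comparison`: both
#'   `selection_report`s, a side-by-side metrics table and the McNemar
#'   row comparing the two full models.
#' @export
compare_universes <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cohort <- load_cohort(config)
  combined <- feature_universe(cohort, "combined")
  ados <- feature_universe(cohort, "ados_only")
  if (length(ados) == 0 || length(ados) == length(combined)) {
    abort("universe comparison needs both ADOS and ADI-R items in the cohort")
  }
  filtered <- filter_complete_cases(cohort, combined)
  sel <- config$selection
  sel$rf$seed <- config$seed
  plan <- make_split(filtered, config$seed, scheme = sel$cv_scheme)
  log_msg(config, "INFO", "paired comparison on %d complete cases (%d validation)",
          nrow(filtered), length(plan$validation_ids))
  clamp_ks <- function(ks, n) if (is.null(ks)) NULL else ks[ks <= n]
  reports <- list(
    combined = select_models(filtered, plan, sel, combined,
                             ks = clamp_ks(config$ks, length(combined))),
    ados_only = select_models(filtered, plan, sel, ados,
                              ks = clamp_ks(config$ks, length(ados)))
  )
  meta <- cohort_items(cohort)
  table <- dplyr::bind_rows(
    dplyr::mutate(metrics_table(reports$combined), universe = "combined", .before = 1),
    dplyr::mutate(metrics_table(reports$ados_only), universe = "ados_only", .before = 1)
  )
  full_vs_full <- mcnemar_compare(
    dplyr::inner_join(
      dplyr::select(reports$combined$models[[as.character(length(combined))]]$validation_predictions,
                    "subject_id", "label", pred_combined = "pred"),
      dplyr::select(reports$ados_only$models[[as.character(length(ados))]]$validation_predictions,
                    "subject_id", pred_ados = "pred"),
      by = "subject_id"
    ),
    pred_a = .data$pred_combined, pred_b = .data$pred_ados,
    method = config$selection$mcnemar_method
  )
  if (!is.null(config$out_dir)) {
    if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
    hash <- config_hash(config)
    write_csv_commented(table, file.path(config$out_dir, "universe_comparison.csv"), hash)
    write_csv_commented(full_vs_full,
                        file.path(config$out_dir, "universe_mcnemar.csv"), hash)
  }
  structure(list(reports = reports, table = table, mcnemar_full = full_vs_full,
                 plan = plan, config = config),
            class = "universe_comparison")
}

#' Load a run configuration from YAML or JSON
#'
#' Reads the file, rebuilds the nested [cohort_spec()], [rf_config()] and
#' [selection_config()] objects and returns a validated [run_config()].
#'
#' @param path `.yaml`/`.yml` or `.json` configuration file.
#' @return A [run_config()].
#' @export
load_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  spec <- NULL
  if (!is.null(raw$spec)) {
    items_raw <- raw$spec$items
    items <- if (is.data.frame(items_raw)) {
      tibble::as_tibble(items_raw)
    } else {
      dplyr::bind_rows(lapply(items_raw, tibble::as_tibble))
    }
    spec <- cohort_spec(
      n_asd = raw$spec$n_asd, n_nonasd = raw$spec$n_nonasd, items = items,
      adi_missing_fraction = raw$spec$adi_missing_fraction %||% 0,
      seed = raw$spec$seed %||% raw$seed %||% 1L
    )
  }
  rf_args <- raw$selection$rf %||% list()
  sel_args <- raw$selection[setdiff(names(raw$selection), "rf")] %||% list()
  sel <- do.call(selection_config, c(sel_args, list(rf = do.call(rf_config, rf_args))))
  run_config(
    spec = spec,
    matrix_file = raw$matrix_file, items_file = raw$items_file,
    labels_file = raw$labels_file,
    universe = raw$universe %||% "combined",
    selection = sel,
    out_dir = raw$out_dir,
    seed = raw$seed %||% 1L,
    ks = raw$ks,
    log_level = raw$log_level %||% "INFO"
  )
}
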