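#' Run the full rank-aggregation-with-re-balance workflow
#'
#' One call chains the whole screening pipeline on a two-class table:
#' re-balance the classes (one of the seven [resampling] cases), rank the
#' features of the re-balanced table with the eight filter methods, fuse the
#' rankings by cross-entropy footrule minimisation, pick the number of key
#' features by stratified cross-validated AUCPRC with a random forest, and
#' report the screening metrics at that size.
#'
#' A single `seed` fans out deterministically into one child seed per stage,
#' so two runs with the same input and configuration produce identical
#' reports.
#'
#' @inheritParams apply_case
#' @inheritParams select_top_k_cv
#' @param ce A [ce_control()] list for the aggregation stage.
#' @param relieff_k,rvalue_k,rvalue_theta Filter parameters, see
#'   [rank_all_filters()].
#' @param cv_resample How the CV evaluation treats re-balancing:
#'   `"within_fold"` (default) cross-validates the *original* table and
#'   re-applies the case inside each training fold, which keeps synthetic
#'   rows out of the held-out folds; `"pre_split"` cross-validates the
#'   re-balanced table directly (the whole-dataset workflow).
#' @param out_dir Optional directory; when given, every intermediate artifact
#'   (re-balanced table, rank lists, aggregation report, AUCPRC curve,
#'   metrics, configuration) is written there as CSV/JSON.
#' @param seed Integer seed for the whole run.
#' @return An object of class `rar_run` with elements `resample`,
#'   `ranklists`, `aggregation`, `topk`, `metrics`, `config` and `seeds`.
#' @examples
#' \donttest{
#' tbl <- generate_two_class_gaussian(case_one_config(ratio = 3), seed = 4)
#' run <- run_rar(tbl, case = 6, folds = 3, trees = 100, seed = 1)
#' run$topk$k_opt
#' }
#' @export
run_rar <- function(data, label = "class", positive = NULL, case = 1L,
                    folds = 5L, trees = 500L, smote_k = 5L,
                    relieff_k = 10L, rvalue_k = 5L,
                    rvalue_theta = rvalue_k / 2,
                    ce = ce_control(),
                    cv_resample = c("within_fold", "pre_split"),
                    out_dir = NULL, seed = NULL) {
  cv_resample <- match.arg(cv_resample)
  ft <- as_feature_table(data, label, positive)
  seeds <- with_seed_maybe(seed, sample.int(1e9, 4))
  config <- list(case = as.integer(case), folds = folds, trees = trees,
                 smote_k = smote_k, relieff_k = relieff_k,
                 rvalue_k = rvalue_k, rvalue_theta = rvalue_theta,
                 cv_resample = cv_resample, seed = seed,
                 positive = ft$positive, label = ft$label)
  config$hash <- rlang::hash(config)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  res <- stage("resample", apply_case(ft, case, smote_k = smote_k,
                                      seed = seeds[1]))
  ranks <- stage("rank", rank_all_filters(res$table, relieff_k = relieff_k,
                                          rvalue_k = rvalue_k,
                                          rvalue_theta = rvalue_theta))
  agg <- stage("aggregate", aggregate_ce(ranks, control = ce, seed = seeds[2]))
  topk <- stage("select_k", {
    if (cv_resample == "within_fold") {
      select_top_k_cv(ft, agg$ranking, folds = folds, trees = trees,
                      resample_case = if (case == 1L) NULL else case,
                      seed = seeds[3])
    } else {
      select_top_k_cv(res$table, agg$ranking, folds = folds, trees = trees,
                      seed = seeds[3])
    }
  })
  metrics <- stage("metrics", metric_report(topk))
  metrics$k_opt <- topk$k_opt

  out <- structure(
    list(resample = res, ranklists = ranks, aggregation = agg, topk = topk,
         metrics = metrics, config = config, seeds = seeds),
    class = "rar_run")
  if (!is.null(out_dir)) write_run_report(out, out_dir)
  out
}

#' @export
print.rar_run <- function(x, ...) {
  cat(sprintf("<rar_run> case %d | config %s\n", x$config$case, x$config$hash))
  print(x$resample)
  print(x$aggregation)
  cat(sprintf("k_opt = %d | Gmean %.3f  F1 %.3f  AUCROC %.3f  AUCPRC %.3f\n",
              x$metrics$k_opt, x$metrics$gmean, x$metrics$f1,
              x$metrics$auc_roc, x$metrics$auc_prc))
  invisible(x)
}

write_run_report <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(as_tibble(run$resample),
                   file.path(out_dir, "resampled_table.csv"))
  readr::write_csv(as_tibble(as.data.frame(run$ranklists)),
                   file.path(out_dir, "rank_lists.csv"))
  readr::write_csv(tidy(run$aggregation),
                   file.path(out_dir, "aggregation_report.csv"))
  readr::write_csv(run$topk$curve, file.path(out_dir, "aucprc_curve.csv"))
  readr::write_csv(run$metrics, file.path(out_dir, "metrics.csv"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    writeLines(jsonlite::toJSON(run$config, auto_unbox = TRUE, null = "null",
                                pretty = TRUE),
               file.path(out_dir, "config.json"))
  }
  invisible(out_dir)
}

#' Paths to the bundled method-comparison tables
#'
#' The package ships plain-text transcriptions of the published
#' method-comparison tables (Gmean, F1, AUCROC and AUCPRC of rank aggregation
#' and the eight filters on five metabolomics datasets under the seven
#' re-balancing cases) plus the dataset summary table.
#'
#' @return A named character vector of file paths.
#' @export
rar_table_fixtures <- function() {
  files <- c(gmean = "screening_gmean.tsv", f1 = "screening_f1.tsv",
             aucroc = "screening_aucroc.tsv", aucprc = "screening_aucprc.tsv")
  vapply(files, function(f) system.file("extdata", f, package = "rarank"),
         character(1))
}

#' Summary of the benchmark datasets
#'
#' Returns the bundled summary of the five metabolomics benchmark datasets
#' (feature and sample counts per class) with the imbalance ratio recomputed
#' as majority / minority, rounded to two decimals, next to the published
#' value.
#'
#' @return A tibble with one row per dataset and a `ratio` column computed
#'   from the class sizes.
#' @export
dataset_summary <- function() {
  path <- system.file("extdata", "dataset_summary.tsv", package = "rarank")
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  # half-up decimal rounding, as used for the printed ratios (21/8 -> 2.63)
  df$ratio <- floor(df$majority / df$minority * 100 + 0.5) / 100
  df
}

#' Summarise the method-comparison tables
#'
#' Reads the four bundled metric tables (or user-supplied files in the same
#' layout) and reports the three headline comparisons, counting ties as
#' reaching the maximum:
#'
#' * `ra_vs_filters_case1` — on the imbalanced datasets without re-balancing,
#'   how often plain rank aggregation (RA) reaches the row maximum against
#'   the eight filters (16 rows: 4 datasets x 4 metrics).
#' * `rar_vs_filters_cases2_7` — under the six re-balancing cases, how often
#'   re-balanced rank aggregation (RAR) reaches the row maximum against the
#'   filters (96 rows).
#' * `rar_vs_ra` — how often a re-balanced RAR value is at least the
#'   no-re-balance RA value of the same dataset and metric (96 comparisons).
#'
#' @param files Named character vector of the four table paths (`gmean`,
#'   `f1`, `aucroc`, `aucprc`); defaults to the bundled transcriptions.
#' @param include_balanced Also count the balanced dataset's case-1 row in
#'   the first comparison (off by default).
#' @return A tibble with one row per comparison: `comparison`, `count`, `n`,
#'   `percent`.
#' @examples
#' summarize_tables()
#' @export
summarize_tables <- function(files = rar_table_fixtures(),
                             include_balanced = FALSE) {
  filters <- c("t_test", "fisher", "hellinger", "relief", "relieff",
               "info_gain", "gini", "r_value")
  needed <- c("dataset", "case", "ra", "rar", filters)
  tabs <- purrr::imap(files, function(path, metric) {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    missing_cols <- setdiff(needed, names(df))
    if (length(missing_cols)) {
      abort(sprintf("Fixture '%s' lacks column(s): %s", path,
                    paste(missing_cols, collapse = ", ")))
    }
    df$metric <- metric
    df
  })
  all_tabs <- dplyr::bind_rows(tabs)
  # the balanced dataset only ever runs without re-balancing; identify it as
  # the dataset that never appears under cases 2-7
  run_cases <- all_tabs |>
    dplyr::distinct(.data$dataset, .data$case) |>
    dplyr::count(.data$dataset)
  balanced_ds <- run_cases$dataset[run_cases$n == 1]

  case1 <- dplyr::filter(all_tabs, .data$case == 1,
                         include_balanced | !.data$dataset %in% balanced_ds)
  cmp1 <- rowmax_proportion(case1, "ra", filters)

  rebal <- dplyr::filter(all_tabs, .data$case != 1)
  cmp2 <- rowmax_proportion(rebal, "rar", filters)

  ra_ref <- all_tabs |>
    dplyr::filter(.data$case == 1) |>
    dplyr::select("dataset", "metric", ra_case1 = "ra")
  paired <- dplyr::left_join(rebal, ra_ref, by = c("dataset", "metric")) |>
    dplyr::filter(!is.na(.data$rar), !is.na(.data$ra_case1))
  cmp3 <- tibble(count = sum(paired$rar >= paired$ra_case1),
                 n = nrow(paired),
                 percent = round(100 * sum(paired$rar >= paired$ra_case1) /
                                   nrow(paired), 2))

  dplyr::bind_rows(
    dplyr::mutate(cmp1, comparison = "ra_vs_filters_case1", .before = 1),
    dplyr::mutate(cmp2, comparison = "rar_vs_filters_cases2_7", .before = 1),
    dplyr::mutate(cmp3, comparison = "rar_vs_ra", .before = 1))
}
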