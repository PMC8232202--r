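#' Threshold metrics from confusion counts
#'
#' Computes the geometric mean of sensitivity and specificity (Gmean) and the
#' F1 score (harmonic mean of precision and recall) from the four confusion
#' counts. Ratios with zero denominators are reported as 0 with a warning,
#' which is the conventional reading for a classifier that never predicts the
#' positive class.
#'
#' @param tp,fp,tn,fn Nonnegative confusion counts; there must be at least one
#'   actual positive (`tp + fn > 0`) and one actual negative (`tn + fp > 0`).
#' @return A one-row tibble with `tpr`, `tnr`, `precision`, `recall`,
#'   `gmean` and `f1`.
#' @examples
#' threshold_metrics(tp = 3, fp = 2, tn = 8, fn = 1)
#' @export
threshold_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) abort("Confusion counts must be nonnegative.")
  if (tp + fn == 0) abort("No actual positives: metrics undefined.")
  if (tn + fp == 0) abort("No actual negatives: metrics undefined.")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warn(sprintf("%s has a zero denominator; reported as 0.", what))
      return(0)
    }
    num / den
  }
  tpr <- tp / (tp + fn)
  tnr <- tn / (tn + fp)
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- tpr
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  tibble(tpr = tpr, tnr = tnr, precision = precision, recall = recall,
         gmean = sqrt(tpr * tnr), f1 = f1)
}

# internal: interpret labels as logical positives
as_positive_indicator <- function(labels, positive = NULL) {
  if (is.logical(labels)) return(labels)
  lv <- unique(as.character(labels))
  if (length(lv) < 2L) abort("Scores for a single class: AUC undefined.")
  if (length(lv) > 2L) abort("Labels must be binary.")
  if (is.null(positive)) {
    tab <- table(as.character(labels))
    positive <- names(tab)[which.min(tab)]
  }
  as.character(labels) == as.character(positive)
}

#' Area under the ROC curve
#'
#' Mann-Whitney estimator: the probability that a randomly chosen positive
#' scores above a randomly chosen negative, with score ties counted 1/2. It
#' is invariant under strictly monotone transformations of the scores.
#'
#' @param scores Numeric classifier scores (larger means more positive).
#' @param labels Binary labels (logical, factor or character).
#' @param positive Label of the positive class; defaults to the rarer one.
#' @return The AUC in `[0, 1]`.
#' @export
auc_roc <- function(scores, labels, positive = NULL) {
  pos <- as_positive_indicator(labels, positive)
  n1 <- sum(pos); n2 <- sum(!pos)
  if (n1 == 0 || n2 == 0) abort("Both classes must be present.")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Area under the precision-recall curve
#'
#' Default estimator is average precision: the sum over descending score
#' thresholds of the precision at each threshold weighted by the recall
#' increment, with tied scores processed as one block (so constant scores
#' yield the prevalence exactly). A trapezoidal PR integration is available
#' but is known to be optimistic and is not the default.
#'
#' @inheritParams auc_roc
#' @param method `"average_precision"` (default) or `"trapezoid"`.
#' @return The area in `[0, 1]`.
#' @export
auc_prc <- function(scores, labels, positive = NULL,
                    method = c("average_precision", "trapezoid")) {
  method <- match.arg(method)
  pos <- as_positive_indicator(labels, positive)
  n1 <- sum(pos)
  if (n1 == 0) abort("No positives: precision-recall area undefined.")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  grp_end <- cumsum(rle(s)$lengths)       # last index of each tie block
  tp <- cumsum(p)[grp_end]
  np <- grp_end                            # predicted positives at each cut
  precision <- tp / np
  recall <- tp / n1
  d_recall <- diff(c(0, recall))
  if (method == "average_precision") {
    sum(precision * d_recall)
  } else {
    prev_prec <- c(1, precision[-length(precision)])
    sum((precision + prev_prec) / 2 * d_recall)
  }
}

# internal: deterministic stratified fold assignment
stratified_folds <- function(y, folds, seed = NULL) {
  if (min(sum(y == 1L), sum(y == 0L)) < folds) {
    abort(sprintf(
      "Cannot build %d stratified folds: the smaller class has only %d samples.",
      folds, min(sum(y == 1L), sum(y == 0L))))
  }
  with_seed_maybe(seed, {
    fold <- integer(length(y))
    for (cl in c(0L, 1L)) {
      idx <- which(y == cl)
      fold[sample(idx)] <- rep_len(seq_len(folds), length(idx))
    }
    fold
  })
}

#' Cross-validated choice of the number of top-ranked features
#'
#' For each `k` from 1 to p, restricts the table to the `k` top-ranked
#' features, fits a random forest (500 trees by default) on each training
#' fold and scores the held-out fold with the area under the precision-recall
#' curve; the per-fold areas are averaged. `k_opt` is the smallest `k`
#' attaining the maximal mean area (parsimony tie-break).
#'
#' Optionally a re-balancing case is applied *inside* each training fold
#' (`resample_case`), which keeps the held-out fold untouched and avoids
#' information leaking from synthetic rows; pass an already re-balanced table
#' instead if the whole-dataset workflow is wanted.
#'
#' @inheritParams random_oversample
#' @param ranking A `rar_ranking` (or feature/rank tibble), e.g. the
#'   consensus list of [aggregate_ce()].
#' @param folds Number of stratified CV folds. Default 5.
#' @param trees Random-forest size. Default 500.
#' @param resample_case Optional case id (1-7) applied to each training fold.
#' @param seed Integer seed driving fold assignment, per-fold resampling and
#'   the forests.
#' @return An object of class `rar_topk`: `k_opt`, the `curve` tibble
#'   (`k`, `mean_aucprc`, `sd_aucprc`), and the out-of-fold scores at
#'   `k_opt`. `autoplot()` draws the curve.
#' @export
select_top_k_cv <- function(data, ranking, label = "class", positive = NULL,
                            folds = 5L, trees = 500L, resample_case = NULL,
                            seed = NULL) {
  ft <- as_feature_table(data, label, positive)
  rk <- as_rank_vector(ranking)
  if (!setequal(names(rk), ft$feature_names)) {
    abort("`ranking` must cover exactly the features of `data`.")
  }
  order_feats <- names(rk)[order(rk)]
  p <- length(order_feats)
  seeds <- with_seed_maybe(seed, sample.int(1e9, 2 + folds))
  fold <- stratified_folds(ft$y, folds, seed = seeds[1])
  # per-fold predictions for every k, computed fold-first so each forest seed
  # is reused across k
  oof <- matrix(NA_real_, nrow(ft$X), p)
  for (f in seq_len(folds)) {
    tr_idx <- which(fold != f)
    te_idx <- which(fold == f)
    tr_ft <- ft_rebuild(ft, ft$X[tr_idx, , drop = FALSE], ft$y[tr_idx])
    if (!is.null(resample_case)) {
      tr_ft <- apply_case(tr_ft, resample_case, seed = seeds[2 + f])$table
    }
    for (k in seq_len(p)) {
      feats <- order_feats[seq_len(k)]
      df_tr <- data.frame(tr_ft$X[, feats, drop = FALSE],
                          .y = factor(tr_ft$y, levels = c(0, 1)))
      fit <- ranger::ranger(.y ~ ., data = df_tr, num.trees = trees,
                            probability = TRUE, seed = seeds[2] + f,
                            num.threads = 1)
      pr <- stats::predict(fit, data.frame(ft$X[te_idx, feats, drop = FALSE]),
                           num.threads = 1)$predictions[, "1"]
      oof[te_idx, k] <- pr
    }
  }
  per_fold <- tidyr::expand_grid(k = seq_len(p), fold = seq_len(folds))
  per_fold$aucprc <- purrr::map2_dbl(per_fold$k, per_fold$fold, function(k, f) {
    idx <- which(fold == f)
    auc_prc(oof[idx, k], ft$y[idx] == 1L)
  })
  curve <- per_fold |>
    dplyr::group_by(.data$k) |>
    dplyr::summarise(mean_aucprc = mean(.data$aucprc),
                     sd_aucprc = sd(.data$aucprc), .groups = "drop")
  k_opt <- curve$k[which.max(curve$mean_aucprc)]   # first max = smallest k
  structure(list(k_opt = k_opt, curve = curve,
                 oof_scores = oof[, k_opt], truth = ft$y == 1L,
                 folds = folds, trees = trees, seed = seed,
                 features = order_feats),
            class = "rar_topk")
}

#' @export
print.rar_topk <- function(x, ...) {
  cat(sprintf("<rar_topk> k_opt = %d (mean AUCPRC %.3f over %d folds)\n",
              x$k_opt, max(x$curve$mean_aucprc), x$folds))
  invisible(x)
}

#' @rdname select_top_k_cv
#' @param x,object A `rar_topk` object.
#' @param ... Unused.
#' @export
tidy.rar_topk <- function(x, ...) x$curve

#' @rdname select_top_k_cv
#' @export
glance.rar_topk <- function(x, ...) {
  tibble(k_opt = x$k_opt, max_mean_aucprc = max(x$curve$mean_aucprc),
         folds = x$folds, trees = x$trees)
}

#' @rdname select_top_k_cv
#' @export
autoplot.rar_topk <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$k, y = .data$mean_aucprc)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_aucprc - .data$sd_aucprc,
                                      ymax = .data$mean_aucprc + .data$sd_aucprc),
                         fill = "grey85") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k_opt, linetype = 2, colour = "red") +
    ggplot2::labs(x = "number of top-ranked features k",
                  y = "mean out-of-fold AUCPRC") +
    ggplot2::theme_minimal()
}

#' Metric report from out-of-fold scores
#'
#' Summarises a `rar_topk` result (or raw scores) into the four screening
#' metrics: Gmean and F1 from the 0.5-thresholded scores, plus AUCROC and
#' AUCPRC.
#'
#' @param scores Either a `rar_topk` object or a numeric score vector.
#' @param truth Logical positives (ignored when `scores` is `rar_topk`).
#' @param threshold Probability cutoff for the hard-label metrics. Default
#'   0.5.
#' @return A one-row tibble with `gmean`, `f1`, `auc_roc`, `auc_prc` and the
#'   confusion counts they derive from.
#' @export
metric_report <- function(scores, truth = NULL, threshold = 0.5) {
  if (inherits(scores, "rar_topk")) {
    truth <- scores$truth
    scores <- scores$oof_scores
  }
  pred <- scores >= threshold
  tm <- threshold_metrics(tp = sum(pred & truth), fp = sum(pred & !truth),
                          tn = sum(!pred & !truth), fn = sum(!pred & truth))
  tibble(gmean = tm$gmean, f1 = tm$f1,
         auc_roc = auc_roc(scores, truth),
         auc_prc = auc_prc(scores, truth),
         tp = sum(pred & truth), fp = sum(pred & !truth),
         tn = sum(!pred & !truth), fn = sum(!pred & truth))
}

#' Proportion of rows where a focal column reaches the row maximum
#'
#' Counts the rows (optionally after filtering) in which the focal column is
#' at least as large as every comparison column — ties count as reaching the
#' maximum. Rows with a missing focal or comparison cell are skipped with a
#' warning.
#'
#' @param data A data frame of numeric results.
#' @param focal Name of the focal column.
#' @param comparison Character vector of comparison column names.
#' @param row_filter Optional logical vector (or one-sided formula evaluated
#'   in `data`) selecting rows before counting.
#' @return A one-row tibble with `count`, `n` and `percent`
#'   (`100 * count / n`, rounded to 2 decimals).
#' @export
rowmax_proportion <- function(data, focal, comparison, row_filter = NULL) {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(c(focal, comparison), names(data))
  if (length(missing_cols)) {
    abort(sprintf("Columns not found: %s", paste(missing_cols, collapse = ", ")))
  }
  keep <- rep(TRUE, nrow(data))
  if (!is.null(row_filter)) {
    if (inherits(row_filter, "formula")) {
      keep <- rlang::eval_tidy(row_filter[[2]], data = data)
    } else {
      keep <- row_filter
    }
  }
  sub <- data[keep, , drop = FALSE]
  vals <- as.matrix(sub[c(focal, comparison)])
  complete <- stats::complete.cases(vals)
  if (any(!complete)) {
    warn(sprintf("%d row(s) skipped due to missing cells.", sum(!complete)))
    vals <- vals[complete, , drop = FALSE]
  }
  hit <- vals[, 1] >= apply(vals[, -1, drop = FALSE], 1, max)
  tibble(count = sum(hit), n = nrow(vals),
         percent = round(100 * sum(hit) / nrow(vals), 2))
}
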