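#' Construct a two-class feature table
#'
#' A feature table holds a numeric sample-by-feature matrix together with a
#' binary class label. The positive class is the minority class by convention
#' (ties allowed), which matches how screening metrics for imbalanced data are
#' oriented throughout the package.
#'
#' @param data A data frame with one label column and numeric feature columns,
#'   or an existing `feature_table` (returned unchanged).
#' @param label Name of the label column. Default `"class"`.
#' @param positive Value of `label` identifying the positive (minority) class.
#'   Defaults to the rarer label; for exactly balanced data the first label in
#'   its frequency table is used.
#'
#' @return An object of class `feature_table`: a list with the feature matrix
#'   `X`, a 0/1 vector `y` (1 = positive class), `feature_names`, the label
#'   column name and the two class labels.
#'
#' @examples
#' df <- data.frame(class = rep(c("a", "b"), c(3, 5)),
#'                  x1 = rnorm(8), x2 = rnorm(8))
#' ft <- as_feature_table(df)
#' ft
#' @export
as_feature_table <- function(data, label = "class", positive = NULL) {
  if (inherits(data, "feature_table")) {
    return(data)
  }
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame or a feature_table.")
  }
  if (!label %in% names(data)) {
    abort(sprintf("Label column '%s' not found in `data`.", label))
  }
  y_raw <- as.character(data[[label]])
  if (anyNA(y_raw)) abort("Label column contains missing values.")
  counts <- table(y_raw)
  if (length(counts) != 2L) {
    abort(sprintf("Label column must have exactly 2 classes, found %d.",
                  length(counts)))
  }
  if (is.null(positive)) {
    positive <- names(counts)[which.min(counts)]
  }
  positive <- as.character(positive)
  if (!positive %in% names(counts)) {
    abort(sprintf("Positive label '%s' not present in the data.", positive))
  }
  negative <- setdiff(names(counts), positive)
  if (counts[[positive]] > counts[[negative]]) {
    abort(sprintf(paste0(
      "Positive class '%s' (n = %d) is larger than '%s' (n = %d); ",
      "the positive class must be the minority (or equal)."),
      positive, counts[[positive]], negative, counts[[negative]]))
  }
  feats <- setdiff(names(data), label)
  if (length(feats) < 2L) abort("At least 2 feature columns are required.")
  X <- as.matrix(data[feats])
  if (!is.numeric(X)) abort("All feature columns must be numeric.")
  if (!all(is.finite(X))) abort("Feature columns contain missing or non-finite values.")
  y <- as.integer(y_raw == positive)
  if (sum(y) < 2L || sum(1L - y) < 2L) {
    abort("Each class must have at least 2 samples.")
  }
  structure(
    list(X = X, y = y, feature_names = feats,
         label = label, positive = positive, negative = negative),
    class = "feature_table")
}

#' Read a feature table from a delimited text file
#'
#' @param path CSV or TSV file with a header row; the delimiter is taken from
#'   the file extension (`.tsv`/`.txt` means tab, anything else comma).
#' @inheritParams as_feature_table
#' @return A [feature_table][as_feature_table].
#' @export
read_feature_table <- function(path, label = "class", positive = NULL) {
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  as_feature_table(as.data.frame(df), label = label, positive = positive)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table> %d samples x %d features | positive '%s' n1 = %d, negative '%s' n2 = %d\n",
    nrow(x$X), ncol(x$X), x$positive, sum(x$y), x$negative, sum(1L - x$y)))
  invisible(x)
}

#' @export
as_tibble.feature_table <- function(x, ...) {
  out <- as_tibble(as.data.frame(x$X))
  out[[x$label]] <- ifelse(x$y == 1L, x$positive, x$negative)
  out[c(x$label, x$feature_names)]
}

#' @export
dim.feature_table <- function(x) dim(x$X)

# internal: class sizes and per-class submatrices
ft_sizes <- function(ft) c(n1 = sum(ft$y), n2 = sum(1L - ft$y))

ft_split <- function(ft) {
  list(X1 = ft$X[ft$y == 1L, , drop = FALSE],
       X2 = ft$X[ft$y == 0L, , drop = FALSE])
}

# internal: rebuild a feature_table from a matrix and 0/1 labels, keeping the
# label vocabulary of a template table
ft_rebuild <- function(template, X, y) {
  structure(
    list(X = X, y = as.integer(y), feature_names = template$feature_names,
         label = template$label, positive = template$positive,
         negative = template$negative),
    class = "feature_table")
}
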