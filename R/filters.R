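#' Filter scores for two-class feature screening
#'
#' Each `score_*()` function computes one per-feature statistic that measures
#' how well a feature separates the positive (minority) from the negative
#' (majority) class, returning a score tibble that [rank_from_scores()] turns
#' into an importance ranking. All eight scorers share the same calling
#' convention: a data frame (or [feature_table][as_feature_table]) in, a
#' tibble out, so they compose with the pipe.
#'
#' Orientation differs between statistics: for the t statistic, Fisher score,
#' Hellinger distance, Relief, ReliefF and information gain a *larger* score
#' means a more important feature; for the Gini split index and the R-value a
#' *smaller* score does. The orientation is carried as an attribute and
#' consumed by [rank_from_scores()].
#'
#' @param data A data frame or [feature_table][as_feature_table].
#' @param label,positive Passed to [as_feature_table()] when `data` is a
#'   plain data frame.
#' @return A tibble of class `rar_scores` with columns `feature` and `score`,
#'   plus attributes `method` and `orientation`.
#' @name filter_scores
NULL

new_scores <- function(feature, score, method, orientation) {
  out <- tibble(feature = feature, score = as.numeric(score))
  attr(out, "method") <- method
  attr(out, "orientation") <- orientation
  class(out) <- c("rar_scores", class(out))
  out
}

#' @export
print.rar_scores <- function(x, ...) {
  cat(sprintf("<rar_scores> method '%s' (%s)\n", attr(x, "method"),
              attr(x, "orientation")))
  NextMethod()
}

#' @describeIn filter_scores absolute Welch two-sample t statistic. Features
#'   with identical values (no variance, no mean gap) score 0 with a warning;
#'   a nonzero mean gap over zero variance scores `Inf`.
#' @export
score_t_test <- function(data, label = "class", positive = NULL) {
  ft <- as_feature_table(data, label, positive)
  sp <- ft_split(ft)
  n1 <- nrow(sp$X1); n2 <- nrow(sp$X2)
  m1 <- colMeans(sp$X1); m2 <- colMeans(sp$X2)
  v1 <- apply(sp$X1, 2, var); v2 <- apply(sp$X2, 2, var)
  se <- sqrt(v1 / n1 + v2 / n2)
  gap <- m1 - m2
  score <- abs(gap) / se
  degenerate <- se == 0 & gap == 0
  if (any(degenerate)) {
    warn(sprintf("t statistic undefined (zero variance, zero gap) for: %s; scored 0.",
                 paste(ft$feature_names[degenerate], collapse = ", ")))
    score[degenerate] <- 0
  }
  score[se == 0 & gap != 0] <- Inf
  new_scores(ft$feature_names, score, "t_test", "larger_better")
}

#' @describeIn filter_scores Fisher score, the absolute class-mean gap over
#'   the root of the summed class variances.
#' @export
score_fisher <- function(data, label = "class", positive = NULL) {
  ft <- as_feature_table(data, label, positive)
  sp <- ft_split(ft)
  m1 <- colMeans(sp$X1); m2 <- colMeans(sp$X2)
  v1 <- apply(sp$X1, 2, var); v2 <- apply(sp$X2, 2, var)
  pooled <- v1 + v2
  gap <- m1 - m2
  score <- abs(gap) / sqrt(pooled)
  zero <- pooled == 0
  if (any(zero)) {
    warn(sprintf("Fisher score degenerate (both class variances zero) for: %s.",
                 paste(ft$feature_names[zero], collapse = ", ")))
    score[zero] <- ifelse(gap[zero] == 0, 0, Inf)
  }
  new_scores(ft$feature_names, score, "fisher", "larger_better")
}

#' @describeIn filter_scores squared Hellinger distance (scaled to `[0, 2]`)
#'   between the per-class Gaussians fitted by plug-in sample moments.
#' @export
score_hellinger <- function(data, label = "class", positive = NULL) {
  ft <- as_feature_table(data, label, positive)
  sp <- ft_split(ft)
  m1 <- colMeans(sp$X1); m2 <- colMeans(sp$X2)
  v1 <- apply(sp$X1, 2, var); v2 <- apply(sp$X2, 2, var)
  pooled <- v1 + v2
  if (any(pooled == 0)) {
    abort(sprintf("Hellinger distance undefined (zero pooled variance) for: %s.",
                  paste(ft$feature_names[pooled == 0], collapse = ", ")))
  }
  s1 <- sqrt(v1); s2 <- sqrt(v2)
  score <- 2 - 2 * sqrt(2 * s1 * s2 / pooled) * exp(-(m1 - m2)^2 / (4 * pooled))
  new_scores(ft$feature_names, score, "hellinger", "larger_better")
}

# internal: min-max scale columns to [0, 1]; constant columns map to 0 so they
# do not contribute to distances
minmax_scale <- function(X) {
  rng <- apply(X, 2, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1
  sweep(sweep(X, 2, rng[1, ]), 2, span, "/")
}

# internal: Relief/ReliefF accumulation given hit and miss neighbour index
# matrices (one row per visited instance, k columns)
relief_accumulate <- function(Xs, visit, hits, misses) {
  p <- ncol(Xs)
  s <- numeric(p)
  k <- ncol(hits)
  for (col in seq_len(k)) {
    s <- s - colSums((Xs[visit, , drop = FALSE] - Xs[hits[, col], , drop = FALSE])^2) / k +
      colSums((Xs[visit, , drop = FALSE] - Xs[misses[, col], , drop = FALSE])^2) / k
  }
  s
}

relief_engine <- function(ft, k, n_iter, seed) {
  Xs <- minmax_scale(ft$X)
  n <- nrow(Xs)
  D <- as.matrix(stats::dist(Xs))
  visit <- seq_len(n)
  if (!is.null(n_iter) && n_iter < n) {
    if (is.null(seed)) {
      visit <- sort(sample.int(n, n_iter))
    } else {
      visit <- withr::with_seed(seed, sort(sample.int(n, n_iter)))
    }
  }
  hits <- matrix(0L, length(visit), k)
  misses <- matrix(0L, length(visit), k)
  same_idx <- lapply(c(0L, 1L), function(cl) which(ft$y == cl))
  for (ii in seq_along(visit)) {
    i <- visit[ii]
    own <- setdiff(same_idx[[ft$y[i] + 1L]], i)
    oth <- same_idx[[2L - ft$y[i]]]
    oh <- own[order(D[i, own], own)][seq_len(k)]
    om <- oth[order(D[i, oth], oth)][seq_len(k)]
    hits[ii, ] <- oh
    misses[ii, ] <- om
  }
  relief_accumulate(Xs, visit, hits, misses)
}

#' @describeIn filter_scores Relief: iterates over instances, pulling each
#'   feature's score down by the squared gap to the nearest same-class
#'   neighbour and up by the squared gap to the nearest other-class neighbour.
#'   Distances are Euclidean over all features min-max scaled to `[0, 1]`.
#'   By default every instance is visited once in index order, which makes the
#'   score deterministic; `rng_seed` is only consulted when `n_iter < n`.
#' @param n_iter Number of instances to visit (default all `n`, in order).
#' @param rng_seed Seed for the instance subsample when `n_iter < n`.
#' @export
score_relief <- function(data, label = "class", positive = NULL,
                         n_iter = NULL, rng_seed = NULL) {
  ft <- as_feature_table(data, label, positive)
  s <- relief_engine(ft, k = 1L, n_iter = n_iter, seed = rng_seed)
  new_scores(ft$feature_names, s, "relief", "larger_better")
}

#' @describeIn filter_scores ReliefF: as Relief but averaging over the
#'   `k_neighbors` nearest hits and misses per visited instance. With
#'   `k_neighbors = 1` it reduces exactly to Relief.
#' @param k_neighbors Number of neighbours; default 10, clipped to
#'   `min(n1, n2) - 1`.
#' @export
score_relieff <- function(data, label = "class", positive = NULL,
                          k_neighbors = 10L, n_iter = NULL, rng_seed = NULL) {
  ft <- as_feature_table(data, label, positive)
  if (k_neighbors < 1L) abort("`k_neighbors` must be at least 1.")
  k <- min(as.integer(k_neighbors), min(ft_sizes(ft)) - 1L)
  s <- relief_engine(ft, k = k, n_iter = n_iter, seed = rng_seed)
  new_scores(ft$feature_names, s, "relieff", "larger_better")
}

# internal: binary entropy (base 2) of a pos/total split, vectorised, with
# 0 log 0 = 0
entropy2 <- function(pos, total) {
  p <- pos / total
  q <- 1 - p
  term <- function(z) ifelse(z > 0, -z * log2(z), 0)
  term(p) + term(q)
}

# internal: evaluate all midpoint binary splits of x; returns a list with the
# parent impurity and the vector of child-weighted impurities for `fun`
split_impurities <- function(x, ypos, fun) {
  n <- length(x)
  o <- order(x)
  xs <- x[o]
  ys <- ypos[o]
  cut_at <- which(diff(xs) > 0)          # split between position i and i + 1
  if (length(cut_at) == 0L) return(NULL)
  nL <- cut_at
  posL <- cumsum(ys)[cut_at]
  nR <- n - nL
  posR <- sum(ys) - posL
  (nL / n) * fun(posL, nL) + (nR / n) * fun(posR, nR)
}

#' @describeIn filter_scores information gain of the best binary split:
#'   each continuous feature is discretised at the midpoint threshold that
#'   maximises the entropy reduction (base-2 logarithm). Constant features
#'   gain nothing and score 0.
#' @export
score_info_gain <- function(data, label = "class", positive = NULL) {
  ft <- as_feature_table(data, label, positive)
  parent <- entropy2(sum(ft$y), length(ft$y))
  score <- apply(ft$X, 2, function(x) {
    child <- split_impurities(x, ft$y, entropy2)
    if (is.null(child)) 0 else parent - min(child)
  })
  new_scores(ft$feature_names, score, "info_gain", "larger_better")
}

gini_impurity <- function(pos, total) {
  p <- pos / total
  1 - p^2 - (1 - p)^2
}

#' @describeIn filter_scores Gini index after the best binary split (the
#'   split minimising the child-weighted impurity). Constant features keep the
#'   parent impurity. Smaller is better.
#' @export
score_gini <- function(data, label = "class", positive = NULL) {
  ft <- as_feature_table(data, label, positive)
  parent <- gini_impurity(sum(ft$y), length(ft$y))
  score <- apply(ft$X, 2, function(x) {
    child <- split_impurities(x, ft$y, gini_impurity)
    if (is.null(child)) parent else min(child)
  })
  new_scores(ft$feature_names, score, "gini", "smaller_better")
}

#' @describeIn filter_scores R-value: the fraction of instances whose
#'   `k_neighbors` nearest neighbours *on that feature alone* (self excluded,
#'   distance ties broken by ascending sample index) contain more than `theta`
#'   opposite-class members. An overlap measure: smaller is better.
#' @param theta Opposite-class count threshold; default `k_neighbors / 2`.
#' @export
score_r_value <- function(data, label = "class", positive = NULL,
                          k_neighbors = 5L, theta = k_neighbors / 2) {
  ft <- as_feature_table(data, label, positive)
  n <- nrow(ft$X)
  if (k_neighbors < 1L || k_neighbors >= n) {
    abort("`k_neighbors` must be in [1, n - 1].")
  }
  score <- apply(ft$X, 2, function(x) {
    cnt <- knn_opposite_counts(as.numeric(x), ft$y, as.integer(k_neighbors))
    mean(cnt > theta)
  })
  new_scores(ft$feature_names, score, "r_value", "smaller_better")
}

#' Turn filter scores into an importance ranking
#'
#' Sorts the scores according to their orientation (descending for
#' larger-is-better statistics, ascending otherwise). Ties — including ties at
#' `Inf` — are broken by ascending feature position, so the ranking is a
#' deterministic permutation of the features.
#'
#' @param scores A score tibble from one of the [filter_scores] functions.
#' @return A tibble of class `rar_ranking` with columns `feature` and `rank`
#'   (1 = most important) and a `method` attribute.
#' @export
rank_from_scores <- function(scores) {
  if (!inherits(scores, "rar_scores")) {
    abort("`scores` must be created by one of the score_*() functions.")
  }
  s <- scores$score
  key <- if (identical(attr(scores, "orientation"), "larger_better")) -s else s
  ord <- order(key, seq_along(s))
  out <- tibble(feature = scores$feature[ord], rank = seq_along(s))
  attr(out, "method") <- attr(scores, "method")
  class(out) <- c("rar_ranking", class(out))
  out
}

#' Methods available in [rank_all_filters()]
#' @return Character vector of the eight filter identifiers, in canonical
#'   order.
#' @export
filter_methods <- function() {
  c("t_test", "fisher", "hellinger", "relief", "relieff",
    "info_gain", "gini", "r_value")
}

#' Rank features with all eight filter methods
#'
#' Runs the t test, Fisher score, Hellinger distance, Relief, ReliefF,
#' information gain, Gini index and R-value scorers and converts each score
#' vector into a ranking. The result is the tidy input expected by
#' [aggregate_ranks()], [aggregate_ce()] and [mean_pairwise_tau()].
#'
#' @inheritParams filter_scores
#' @param relieff_k Neighbours for ReliefF (default 10, clipped to the
#'   smaller class size minus one).
#' @param rvalue_k,rvalue_theta Neighbourhood size and threshold for the
#'   R-value (defaults 5 and `k/2`).
#' @param rng_seed Seed forwarded to the Relief family (only used when
#'   subsampling instances).
#' @return A tibble of class `rar_ranklists` with columns `method`, `feature`
#'   and `rank`; exactly one full ranking per method.
#' @examples
#' set.seed(1)
#' df <- data.frame(class = rep(c("a", "b"), each = 10),
#'                  good = c(rnorm(10, 2), rnorm(10)), noise = rnorm(20))
#' rank_all_filters(df)
#' @export
rank_all_filters <- function(data, label = "class", positive = NULL,
                             relieff_k = 10L, rvalue_k = 5L,
                             rvalue_theta = rvalue_k / 2, rng_seed = NULL) {
  ft <- as_feature_table(data, label, positive)
  scorers <- list(
    t_test    = function() score_t_test(ft),
    fisher    = function() score_fisher(ft),
    hellinger = function() score_hellinger(ft),
    relief    = function() score_relief(ft, rng_seed = rng_seed),
    relieff   = function() score_relieff(ft, k_neighbors = relieff_k,
                                         rng_seed = rng_seed),
    info_gain = function() score_info_gain(ft),
    gini      = function() score_gini(ft),
    r_value   = function() score_r_value(ft, k_neighbors = rvalue_k,
                                         theta = rvalue_theta)
  )
  out <- purrr::map2_dfr(scorers, names(scorers), function(f, nm) {
    rk <- tryCatch(rank_from_scores(f()), error = function(e) {
      abort(sprintf("Filter '%s' failed: %s", nm, conditionMessage(e)))
    })
    dplyr::mutate(rk, method = nm, .before = 1)
  })
  out$method <- factor(out$method, levels = filter_methods())
  class(out) <- c("rar_ranklists", class(out))
  out
}
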