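#' Kendall's tau between two feature rankings
#'
#' Pairwise-concordance correlation between two tie-free rankings of the same
#' feature set: the number of concordant minus discordant feature pairs over
#' the number of pairs. +1 means identical orderings, -1 exactly reversed.
#'
#' @param f1,f2 Rankings as produced by [rank_from_scores()] (tibbles with
#'   `feature` and `rank` columns), or named rank vectors.
#' @return A number in `[-1, 1]`.
#' @examples
#' a <- tibble::tibble(feature = c("x", "y", "z"), rank = 1:3)
#' b <- tibble::tibble(feature = c("x", "z", "y"), rank = 1:3)
#' kendall_tau(a, b)
#' @export
kendall_tau <- function(f1, f2) {
  r1 <- as_rank_vector(f1)
  r2 <- as_rank_vector(f2)
  if (!setequal(names(r1), names(r2))) {
    abort("The two rankings cover different feature sets.")
  }
  r2 <- r2[names(r1)]
  p <- length(r1)
  s <- sign(outer(r1, r1, "-")) * sign(outer(r2, r2, "-"))
  sum(s[upper.tri(s)]) / (p * (p - 1) / 2)
}

as_rank_vector <- function(f) {
  if (is.data.frame(f)) {
    if (!all(c("feature", "rank") %in% names(f))) {
      abort("Ranking data frames need `feature` and `rank` columns.")
    }
    r <- as.numeric(f$rank)
    names(r) <- as.character(f$feature)
  } else if (is.numeric(f) && !is.null(names(f))) {
    r <- f
  } else {
    abort("Rankings must be feature/rank tibbles or named rank vectors.")
  }
  if (anyDuplicated(names(r))) abort("Duplicate features in ranking.")
  if (!setequal(r, seq_along(r))) {
    abort("Ranks must be a permutation of 1..p (no ties).")
  }
  r
}

#' Spearman footrule distance between two rankings
#'
#' The sum over features of the absolute difference between their ranks in
#' the two lists. Optionally, a score profile `rank_scores` maps each rank
#' position to a score, in which case each term is additionally weighted by
#' the absolute score difference of the two positions (a weighted footrule
#' for callers whose lists share a score scale; the default is the plain,
#' scale-free distance).
#'
#' @inheritParams kendall_tau
#' @param a,b Rankings over the same feature set.
#' @param rank_scores Optional numeric vector of length p; `rank_scores[r]`
#'   is the score attached to rank position `r`.
#' @return A nonnegative number (0 iff the rankings agree).
#' @export
footrule_distance <- function(a, b, rank_scores = NULL) {
  r1 <- as_rank_vector(a)
  r2 <- as_rank_vector(b)
  if (!setequal(names(r1), names(r2))) {
    abort("The two rankings cover different feature sets.")
  }
  r2 <- r2[names(r1)]
  if (is.null(rank_scores)) {
    sum(abs(r1 - r2))
  } else {
    if (length(rank_scores) != length(r1)) {
      abort("`rank_scores` must have one entry per rank position.")
    }
    sum(abs(rank_scores[r1] - rank_scores[r2]) * abs(r1 - r2))
  }
}

#' Mean pairwise Kendall's tau of a set of rankings
#'
#' Averages [kendall_tau()] over all unordered pairs of lists — the
#' concordance statistic used to quantify how much a panel of filter methods
#' agrees (8 lists give 28 pairs).
#'
#' @param ranklists A `rar_ranklists` tibble ([rank_all_filters()]) or a list
#'   of rankings.
#' @return The mean tau over all `m(m-1)/2` pairs.
#' @export
mean_pairwise_tau <- function(ranklists) {
  lists <- as_ranking_list(ranklists)
  m <- length(lists)
  if (m < 2L) abort("At least two rankings are required.")
  pairs <- utils::combn(m, 2)
  mean(purrr::map_dbl(seq_len(ncol(pairs)), function(j) {
    kendall_tau(lists[[pairs[1, j]]], lists[[pairs[2, j]]])
  }))
}

# internal: normalise ranking input to a named list of feature/rank tibbles
as_ranking_list <- function(ranklists) {
  if (is.data.frame(ranklists) && "method" %in% names(ranklists)) {
    split(ranklists[c("feature", "rank")], ranklists$method, drop = TRUE)
  } else if (is.list(ranklists) && !is.data.frame(ranklists)) {
    ranklists
  } else {
    abort("Expected a rar_ranklists tibble or a list of rankings.")
  }
}

# internal: p x m integer matrix of ranks, rows in the feature order of the
# first list
rank_matrix <- function(lists) {
  f1 <- as_rank_vector(lists[[1]])
  feats <- names(f1)[order(f1)]
  mat <- vapply(lists, function(f) as_rank_vector(f)[feats], numeric(length(feats)))
  if (anyNA(mat)) abort("All rankings must cover the same feature set.")
  storage.mode(mat) <- "integer"
  rownames(mat) <- feats
  mat
}

#' Control parameters for the cross-entropy optimiser
#'
#' @param n_samples Permutations sampled per iteration; default `10 * p^2`
#'   (resolved at run time), minimum 10.
#' @param elite_frac Fraction of best-scoring samples used to refit the
#'   probability matrix. Default 0.1.
#' @param smoothing Weight of the new elite frequencies in the probability
#'   update (1 = replace, smaller = smoother). Default 0.7.
#' @param max_iter Iteration cap. Default 100.
#' @param window Stop once the best objective has not improved for this many
#'   consecutive iterations. Default 5.
#' @return A list of class `ce_control`.
#' @export
ce_control <- function(n_samples = NULL, elite_frac = 0.1, smoothing = 0.7,
                       max_iter = 100L, window = 5L) {
  stopifnot(elite_frac > 0, elite_frac < 1, smoothing > 0, smoothing <= 1,
            max_iter >= 1, window >= 1)
  structure(list(n_samples = n_samples, elite_frac = elite_frac,
                 smoothing = smoothing, max_iter = max_iter,
                 window = as.integer(window)),
            class = "ce_control")
}

new_aggregation <- function(ranking, objective, trace, method, weights,
                            lists, seed, converged = NA) {
  structure(
    list(ranking = ranking, objective = objective, trace = trace,
         method = method, weights = weights, lists = lists, seed = seed,
         iterations = length(trace), converged = converged),
    class = "rar_aggregation")
}

#' Exact rank aggregation by exhaustive enumeration
#'
#' Minimises the weighted footrule objective over *all* permutations of the
#' features — feasible only for small p (at most 8) and used as the exact
#' reference for [aggregate_ce()]. Ties between equally optimal permutations
#' are resolved lexicographically.
#'
#' @inheritParams mean_pairwise_tau
#' @param weights Nonnegative list weights, recycled to sum 1. Default
#'   uniform.
#' @return A `rar_aggregation` object; see [aggregate_ranks()].
#' @export
aggregate_brute_force <- function(ranklists, weights = NULL) {
  lists <- as_ranking_list(ranklists)
  mat <- rank_matrix(lists)
  p <- nrow(mat)
  if (p > 8L) {
    abort("Exhaustive aggregation enumerates p! lists; use aggregate_ce() for p > 8.")
  }
  w <- normalise_weights(weights, ncol(mat))
  perms <- permutations_lex(p)
  obj <- footrule_objectives(perms, mat, w)
  best <- which.min(obj)          # first minimum = lexicographically smallest
  ranking <- perm_to_ranking(perms[best, ], rownames(mat), "aggregate_brute_force")
  new_aggregation(ranking, obj[best], trace = obj[best],
                  method = "brute_force", weights = w, lists = lists,
                  seed = NULL, converged = TRUE)
}

# all permutations of 1..p in lexicographic row order
permutations_lex <- function(p) {
  if (p == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_lex(p - 1L)
  out <- lapply(seq_len(p), function(f) {
    rest <- seq_len(p)[-f]
    cbind(f, matrix(rest[sub], nrow = nrow(sub)))
  })
  m <- do.call(rbind, out)
  storage.mode(m) <- "integer"
  m
}

perm_to_ranking <- function(perm, feats, method) {
  out <- tibble(feature = feats[perm], rank = seq_along(perm))
  attr(out, "method") <- method
  class(out) <- c("rar_ranking", class(out))
  out
}

normalise_weights <- function(weights, m) {
  if (is.null(weights)) weights <- rep(1, m)
  if (length(weights) != m) abort("One weight per ranking list is required.")
  if (any(weights < 0) || sum(weights) == 0) abort("Weights must be nonnegative and not all zero.")
  weights / sum(weights)
}

#' Rank aggregation by cross-entropy Monte Carlo search
#'
#' Finds a consensus ranking minimising the weighted Spearman footrule
#' distance to a set of input rankings. The optimiser maintains a
#' feature-by-position probability matrix (initialised uniform at `1/p`),
#' samples `n_samples` candidate permutations position by position, refits the
#' matrix to the elite fraction with exponential smoothing, and stops when the
#' best objective has been flat for `window` iterations (or at `max_iter`).
#' The best permutation ever seen is returned.
#'
#' @inheritParams aggregate_brute_force
#' @param control A [ce_control()] list.
#' @param seed Optional integer seed; the search is deterministic given the
#'   seed.
#' @return A `rar_aggregation` object with the optimal ranking, its
#'   objective, and the per-iteration best-objective trace.
#' @examples
#' set.seed(7)
#' df <- data.frame(class = rep(c("a", "b"), each = 10),
#'                  x1 = c(rnorm(10, 3), rnorm(10)),
#'                  x2 = c(rnorm(10, 1), rnorm(10)),
#'                  x3 = rnorm(20))
#' agg <- df |> rank_all_filters() |> aggregate_ce(seed = 1)
#' tidy(agg)
#' @export
aggregate_ce <- function(ranklists, weights = NULL, control = ce_control(),
                         seed = NULL) {
  lists <- as_ranking_list(ranklists)
  mat <- rank_matrix(lists)
  p <- nrow(mat)
  w <- normalise_weights(weights, ncol(mat))
  n_samples <- max(10L, as.integer(control$n_samples %||% (10L * p^2)))
  run <- function() {
    P <- matrix(1 / p, p, p)
    best_obj <- Inf
    best_perm <- NULL
    trace <- numeric(0)
    stall <- 0L
    for (it in seq_len(control$max_iter)) {
      perms <- ce_sample_permutations(P, n_samples)
      obj <- footrule_objectives(perms, mat, w)
      n_elite <- max(1L, ceiling(control$elite_frac * n_samples))
      eidx <- order(obj)[seq_len(n_elite)]
      improved <- obj[eidx[1]] < best_obj
      if (improved) {
        best_obj <- obj[eidx[1]]
        best_perm <- perms[eidx[1], ]
      }
      trace <- c(trace, best_obj)
      stall <- if (improved) 0L else stall + 1L
      if (best_obj == 0 || stall >= control$window) break
      elite <- perms[eidx, , drop = FALSE]
      Fhat <- vapply(seq_len(p), function(s) tabulate(elite[, s], nbins = p) / n_elite,
                     numeric(p))
      P <- control$smoothing * Fhat + (1 - control$smoothing) * P
    }
    list(best_perm = best_perm, best_obj = best_obj, trace = trace,
         converged = stall >= control$window || best_obj == 0)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  ranking <- perm_to_ranking(res$best_perm, rownames(mat), "aggregate_ce")
  new_aggregation(ranking, res$best_obj, res$trace, method = "ce",
                  weights = w, lists = lists, seed = seed,
                  converged = res$converged)
}

#' Aggregate a set of feature rankings
#'
#' Front end over [aggregate_ce()] (the default, any p) and
#' [aggregate_brute_force()] (exact, p <= 8).
#'
#' @inheritParams aggregate_ce
#' @param method `"ce"` or `"brute_force"`.
#' @return A `rar_aggregation` object. `tidy()` returns the per-feature
#'   aggregated rank next to every input rank and their mean; `glance()`
#'   returns the objective, iteration count and convergence flag;
#'   `autoplot()` draws the consensus list against the input lists.
#' @export
aggregate_ranks <- function(ranklists, method = c("ce", "brute_force"),
                            weights = NULL, control = ce_control(),
                            seed = NULL) {
  method <- match.arg(method)
  switch(method,
    ce = aggregate_ce(ranklists, weights, control, seed),
    brute_force = aggregate_brute_force(ranklists, weights))
}

#' @export
print.rar_aggregation <- function(x, ...) {
  cat(sprintf("<rar_aggregation> %s | %d lists over %d features | objective %.4g (%d iterations)\n",
              x$method, length(x$lists), nrow(x$ranking), x$objective,
              x$iterations))
  cat("Top of the consensus list:",
      paste(utils::head(x$ranking$feature, 5), collapse = ", "), "...\n")
  invisible(x)
}

#' @rdname aggregate_ranks
#' @param x A `rar_aggregation` object.
#' @param ... Unused.
#' @export
tidy.rar_aggregation <- function(x, ...) {
  wide <- purrr::imap(x$lists, function(f, nm) {
    v <- as_rank_vector(f)
    tibble(feature = names(v), rank = unname(v), method = nm)
  })
  wide <- dplyr::bind_rows(wide) |>
    tidyr::pivot_wider(names_from = "method", values_from = "rank")
  out <- dplyr::left_join(
    tibble(feature = x$ranking$feature, aggregated_rank = x$ranking$rank),
    wide, by = "feature")
  out$mean_rank <- rowMeans(out[setdiff(names(out), c("feature", "aggregated_rank"))])
  out
}

#' @rdname aggregate_ranks
#' @export
glance.rar_aggregation <- function(x, ...) {
  tibble(method = x$method, objective = x$objective,
         iterations = x$iterations, converged = isTRUE(x$converged),
         n_lists = length(x$lists), n_features = nrow(x$ranking))
}

#' @rdname aggregate_ranks
#' @param object A `rar_aggregation` object.
#' @export
autoplot.rar_aggregation <- function(object, ...) {
  td <- tidy(object)
  long <- tidyr::pivot_longer(
    td, cols = -c("feature", "aggregated_rank", "mean_rank"),
    names_to = "method", values_to = "rank")
  td$feature <- factor(td$feature, levels = td$feature)
  long$feature <- factor(long$feature, levels = levels(td$feature))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$feature, y = .data$rank)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$method), colour = "grey70") +
    ggplot2::geom_line(data = td,
                       ggplot2::aes(y = .data$mean_rank, group = 1),
                       colour = "black", linewidth = 0.8) +
    ggplot2::geom_line(data = td,
                       ggplot2::aes(y = .data$aggregated_rank, group = 1),
                       colour = "red", linewidth = 0.9) +
    ggplot2::labs(x = "feature (consensus order)", y = "rank",
                  title = "Consensus ranking (red) vs input lists (grey) and their mean (black)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
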