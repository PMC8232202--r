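#' Configure a two-class Gaussian simulation
#'
#' Describes a two-class multivariate Gaussian sampling design: the majority
#' (negative) class is drawn from `N(0, Sigma)` and the minority (positive)
#' class from `N(mean_shift, Sigma)`. The imbalance `ratio` r splits
#' `n_total` into `n * r / (r + 1)` majority and `n / (r + 1)` minority
#' samples, which must be whole numbers.
#'
#' @param p Number of features.
#' @param mean_shift Numeric vector of length `p`: the class-mean difference.
#' @param sigma Covariance matrix (default identity); must be symmetric
#'   positive definite.
#' @param n_total Total sample size. Default 960.
#' @param ratio Majority-to-minority ratio (1 means balanced). Default 1.
#' @param repeats Monte-Carlo repeats for [concordance_study()]. Default 100.
#' @param rng_seed Optional base seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(p, mean_shift, sigma = NULL, n_total = 960L,
                              ratio = 1, repeats = 100L, rng_seed = NULL) {
  if (length(mean_shift) != p) abort("`mean_shift` must have length p.")
  if (is.null(sigma)) sigma <- diag(p)
  if (!isSymmetric(unname(sigma)) || any(eigen(sigma, symmetric = TRUE,
                                               only.values = TRUE)$values <= 0)) {
    abort("`sigma` must be symmetric positive definite.")
  }
  n1 <- n_total / (ratio + 1)
  n2 <- n_total * ratio / (ratio + 1)
  if (abs(n1 - round(n1)) > 1e-8 || abs(n2 - round(n2)) > 1e-8) {
    abort(sprintf("n_total = %d does not split into whole class sizes at ratio %s:1.",
                  n_total, format(ratio)))
  }
  structure(list(p = as.integer(p), mean_shift = as.numeric(mean_shift),
                 sigma = sigma, n_total = as.integer(n_total), ratio = ratio,
                 n1 = as.integer(round(n1)), n2 = as.integer(round(n2)),
                 repeats = as.integer(repeats), rng_seed = rng_seed),
            class = "simulation_config")
}

#' Simulation designs for the concordance study
#'
#' Two stock designs for studying how much the eight filter rankings agree:
#' case one has eight features, all informative, with mean shifts
#' `(2.4, 2.2, 2.0, 1.8, 1.6, 1.4, 1.2, 1.0)` standard deviations; case two
#' appends eight irrelevant (zero-shift) features to the same design. Both
#' use the identity covariance and 960 samples in total.
#'
#' @inheritParams simulation_config
#' @return A [simulation_config()].
#' @export
case_one_config <- function(ratio = 1, n_total = 960L, repeats = 100L,
                            rng_seed = NULL) {
  simulation_config(p = 8L,
                    mean_shift = c(2.4, 2.2, 2, 1.8, 1.6, 1.4, 1.2, 1),
                    n_total = n_total, ratio = ratio, repeats = repeats,
                    rng_seed = rng_seed)
}

#' @rdname case_one_config
#' @export
case_two_config <- function(ratio = 1, n_total = 960L, repeats = 100L,
                            rng_seed = NULL) {
  simulation_config(p = 16L,
                    mean_shift = c(2.4, 2.2, 2, 1.8, 1.6, 1.4, 1.2, 1,
                                   rep(0, 8)),
                    n_total = n_total, ratio = ratio, repeats = repeats,
                    rng_seed = rng_seed)
}

#' Draw one two-class Gaussian feature table
#'
#' @param cfg A [simulation_config()].
#' @param seed Optional seed overriding `cfg$rng_seed`.
#' @return A [feature_table][as_feature_table] with labels `"case"`
#'   (minority, positive) and `"control"` (majority); features are named
#'   `x1..xp`.
#' @export
generate_two_class_gaussian <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  seed <- seed %||% cfg$rng_seed
  p <- cfg$p
  draw <- function() {
    Z <- matrix(rnorm((cfg$n1 + cfg$n2) * p), ncol = p)
    if (!identical(unname(cfg$sigma), diag(p))) {
      Z <- Z %*% chol(cfg$sigma)
    }
    Z[seq_len(cfg$n1), ] <- sweep(Z[seq_len(cfg$n1), , drop = FALSE], 2,
                                  cfg$mean_shift, "+")
    Z
  }
  X <- with_seed_maybe(seed, draw())
  colnames(X) <- paste0("x", seq_len(p))
  df <- as.data.frame(X)
  df$class <- rep(c("case", "control"), c(cfg$n1, cfg$n2))
  as_feature_table(df, label = "class", positive = "case")
}

#' Ranking-concordance study across imbalance ratios
#'
#' For each imbalance ratio, repeatedly draws a fresh two-class Gaussian
#' table, ranks its features with all eight filters, and records the mean
#' pairwise Kendall tau of the eight rankings. The repeat-averaged mean and
#' its standard deviation are reported per ratio — a direct measure of how
#' class imbalance erodes agreement among filter methods.
#'
#' @param cfg A [simulation_config()] (the `ratio` field is overridden by
#'   each entry of `ratios`).
#' @param ratios Majority:minority ratios to scan. Default
#'   `c(1, 3, 9, 31, 95)`.
#' @param repeats Repeats per ratio; defaults to `cfg$repeats`.
#' @param seed Base seed; every (ratio, repeat) cell gets an independent
#'   child seed derived from it.
#' @return A tibble of class `rar_concordance` with one row per ratio
#'   (`ratio`, `mean_tau`, `sd_tau`, `repeats`) and the per-repeat values in
#'   the `"detail"` attribute. `autoplot()` draws mean +/- sd against the
#'   ratio.
#' @examples
#' \donttest{
#' cs <- concordance_study(case_one_config(), ratios = c(1, 9), repeats = 3,
#'                         seed = 1)
#' cs
#' }
#' @export
concordance_study <- function(cfg, ratios = c(1, 3, 9, 31, 95),
                              repeats = NULL, seed = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  repeats <- repeats %||% cfg$repeats
  seed <- seed %||% cfg$rng_seed
  cells <- tidyr::expand_grid(ratio = ratios, rep = seq_len(repeats))
  child <- with_seed_maybe(seed, sample.int(1e9, nrow(cells)))
  cells$tau <- purrr::map_dbl(seq_len(nrow(cells)), function(i) {
    cfg_i <- simulation_config(cfg$p, cfg$mean_shift, cfg$sigma, cfg$n_total,
                               ratio = cells$ratio[i], repeats = 1L)
    tbl <- generate_two_class_gaussian(cfg_i, seed = child[i])
    mean_pairwise_tau(rank_all_filters(tbl))
  })
  out <- cells |>
    dplyr::group_by(.data$ratio) |>
    dplyr::summarise(mean_tau = mean(.data$tau), sd_tau = sd(.data$tau),
                     repeats = dplyr::n(), .groups = "drop")
  attr(out, "detail") <- cells
  class(out) <- c("rar_concordance", class(out))
  out
}

#' @rdname concordance_study
#' @param object A `rar_concordance` tibble.
#' @param ... Unused.
#' @export
autoplot.rar_concordance <- function(object, ...) {
  df <- as.data.frame(object)
  df$ratio_lab <- factor(paste0(df$ratio, ":1"),
                         levels = paste0(sort(unique(df$ratio)), ":1"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ratio_lab, y = .data$mean_tau,
                                   group = 1)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_tau - .data$sd_tau,
                                        ymax = .data$mean_tau + .data$sd_tau),
                           width = 0.15) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "majority:minority ratio",
                  y = "mean pairwise Kendall tau",
                  title = "Concordance of the eight filter rankings") +
    ggplot2::theme_minimal()
}
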