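#' Re-balancing strategies for class-imbalanced feature tables
#'
#' Seven re-sampling regimes modify the class distribution of a two-class
#' table before ranking:
#'
#' * case 1 — none: the table is passed through untouched.
#' * case 2 — hybrid A: the minority is doubled with SMOTE and the majority
#'   randomly cut to the same size (`2 * n1` each).
#' * case 3 — hybrid B: a fully synthetic table of the original size `n` is
#'   drawn by smoothed bootstrap, classes split `floor(n/2)` (minority) /
#'   `ceiling(n/2)` (majority).
#' * case 4 — over A: minority rows randomly duplicated up to `n2`.
#' * case 5 — over B: smoothed-bootstrap synthetic minority rows added up to
#'   `n2`.
#' * case 6 — under A: majority rows randomly removed down to `n1`.
#' * case 7 — under B: the majority is replaced by `n1` smoothed-bootstrap
#'   draws from itself.
#'
#' All randomness is governed by `seed`; rows carried over from the input are
#' bit-identical to it and flagged `"original"` in the provenance.
#'
#' @name resampling
NULL

new_resample <- function(table, before, after, provenance, case) {
  structure(list(table = table, counts_before = before, counts_after = after,
                 provenance = provenance, case = as.integer(case)),
            class = "rar_resample")
}

#' @export
print.rar_resample <- function(x, ...) {
  cat(sprintf("<rar_resample> case %d | n1 %d -> %d, n2 %d -> %d (%d synthetic rows)\n",
              x$case, x$counts_before[["n1"]], x$counts_after[["n1"]],
              x$counts_before[["n2"]], x$counts_after[["n2"]],
              sum(x$provenance == "synthetic")))
  invisible(x)
}

#' @export
as_tibble.rar_resample <- function(x, ...) {
  out <- as_tibble(x$table)
  out$.provenance <- x$provenance
  out
}

with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' @describeIn resampling grow the minority class to `target_n1` by sampling
#'   original minority rows with replacement.
#' @param data A data frame or [feature_table][as_feature_table].
#' @param label,positive Passed to [as_feature_table()].
#' @param target_n1,target_n2 Target class sizes.
#' @param seed Integer seed for reproducibility.
#' @export
random_oversample <- function(data, target_n1, label = "class",
                              positive = NULL, seed = NULL) {
  ft <- as_feature_table(data, label, positive)
  sz <- ft_sizes(ft)
  if (target_n1 < sz[["n1"]]) {
    abort("`target_n1` is below the current minority size; nothing to duplicate.")
  }
  extra <- target_n1 - sz[["n1"]]
  min_idx <- which(ft$y == 1L)
  dup <- with_seed_maybe(seed, sample(min_idx, extra, replace = TRUE))
  X <- rbind(ft$X, ft$X[dup, , drop = FALSE])
  y <- c(ft$y, rep(1L, extra))
  new_resample(ft_rebuild(ft, X, y),
               before = sz, after = c(n1 = as.integer(target_n1), n2 = sz[["n2"]]),
               provenance = c(rep("original", nrow(ft$X)), rep("synthetic", extra)),
               case = 4L)
}

#' @describeIn resampling shrink the majority class to `target_n2` by
#'   sampling rows to keep without replacement.
#' @export
random_undersample <- function(data, target_n2, label = "class",
                               positive = NULL, seed = NULL) {
  ft <- as_feature_table(data, label, positive)
  sz <- ft_sizes(ft)
  if (target_n2 > sz[["n2"]]) {
    abort("`target_n2` exceeds the current majority size.")
  }
  maj_idx <- which(ft$y == 0L)
  keep_maj <- with_seed_maybe(seed, sort(sample(maj_idx, target_n2)))
  keep <- sort(c(which(ft$y == 1L), keep_maj))
  new_resample(ft_rebuild(ft, ft$X[keep, , drop = FALSE], ft$y[keep]),
               before = sz, after = c(n1 = sz[["n1"]], n2 = as.integer(target_n2)),
               provenance = rep("original", length(keep)),
               case = 6L)
}

#' SMOTE interpolation for the minority class
#'
#' Creates `n_new` synthetic minority points. Each point is
#' `xi + u * (xih - xi)` for a randomly chosen minority seed `xi`, one of its
#' `k` nearest minority neighbours `xih` (Euclidean distance over all
#' features, self excluded, ties by ascending index) and a single scalar
#' `u ~ Uniform(0, 1)` per point — so every synthetic point lies on the
#' segment between its seed and the chosen neighbour.
#'
#' @param minority_X Numeric matrix of minority-class rows (at least 2).
#' @param n_new Number of synthetic rows to create.
#' @param k Neighbourhood size, clipped to `nrow(minority_X) - 1`. Default 5.
#' @param seed Integer seed.
#' @return A `n_new x p` matrix of synthetic rows.
#' @export
smote_generate <- function(minority_X, n_new, k = 5L, seed = NULL) {
  minority_X <- as.matrix(minority_X)
  n <- nrow(minority_X)
  if (n < 2L) abort("SMOTE needs at least 2 minority rows.")
  if (n_new < 0) abort("`n_new` must be nonnegative.")
  if (n_new == 0) return(minority_X[0, , drop = FALSE])
  k <- min(as.integer(k), n - 1L)
  if (k < 1L) abort("`k` must be at least 1.")
  D <- as.matrix(stats::dist(minority_X))
  nn <- t(vapply(seq_len(n), function(i) {
    others <- setdiff(seq_len(n), i)
    others[order(D[i, others], others)][seq_len(k)]
  }, integer(k)))
  with_seed_maybe(seed, {
    seed_idx <- sample.int(n, n_new, replace = TRUE)
    nb_pick <- sample.int(k, n_new, replace = TRUE)
    u <- runif(n_new)
    xi <- minority_X[seed_idx, , drop = FALSE]
    xih <- minority_X[nn[cbind(seed_idx, nb_pick)], , drop = FALSE]
    xi + u * (xih - xi)
  })
}

# internal: per-feature Silverman bandwidths for one class; degenerate
# features (or singleton classes) fall back to 1% of the overall feature sd
silverman_bandwidth <- function(class_X, all_X) {
  nk <- nrow(class_X)
  fallback <- 0.01 * apply(all_X, 2, sd)
  if (nk < 2L) {
    message("Bandwidth fallback: class has a single sample; using 1% of the overall feature scale.")
    return(fallback)
  }
  s <- apply(class_X, 2, sd)
  iqr <- apply(class_X, 2, IQR)
  h <- 0.9 * pmin(s, iqr / 1.34) * nk^(-1 / 5)
  if (any(h == 0)) {
    message(sprintf("Bandwidth fallback for %d degenerate feature(s); using 1%% of the overall feature scale.",
                    sum(h == 0)))
    h[h == 0] <- fallback[h == 0]
  }
  h
}

#' Smoothed-bootstrap synthetic rows
#'
#' Draws synthetic samples by picking an original row of the requested class
#' uniformly at random and perturbing it with a diagonal Gaussian kernel
#' centred at that row. Bandwidths follow Silverman's per-feature rule
#' `0.9 * min(sd, IQR/1.34) * nk^(-1/5)` computed within the class;
#' `bandwidth_scale = 0` degenerates to a plain bootstrap.
#'
#' @inheritParams random_oversample
#' @param m1,m2 Number of synthetic positive / negative rows to draw.
#' @param bandwidth_rule Currently `"silverman"`.
#' @param bandwidth_scale Multiplier on the bandwidths (default 1).
#' @return A tibble of synthetic rows with the label column attached.
#' @export
smoothed_bootstrap <- function(data, m1, m2, label = "class", positive = NULL,
                               bandwidth_rule = "silverman",
                               bandwidth_scale = 1, seed = NULL) {
  ft <- as_feature_table(data, label, positive)
  if (!identical(bandwidth_rule, "silverman")) {
    abort("Only the 'silverman' bandwidth rule is implemented.")
  }
  if (m1 < 0 || m2 < 0) abort("Requested counts must be nonnegative.")
  sp <- ft_split(ft)
  draw <- function(class_X, m) {
    if (m == 0) return(class_X[0, , drop = FALSE])
    h <- silverman_bandwidth(class_X, ft$X) * bandwidth_scale
    idx <- sample.int(nrow(class_X), m, replace = TRUE)
    noise <- matrix(rnorm(m * ncol(class_X)), m) %*% diag(h, ncol(class_X))
    class_X[idx, , drop = FALSE] + noise
  }
  res <- with_seed_maybe(seed, {
    list(pos = draw(sp$X1, m1), neg = draw(sp$X2, m2))
  })
  X <- rbind(res$pos, res$neg)
  out <- as_tibble(as.data.frame(X))
  names(out) <- ft$feature_names
  out[[ft$label]] <- rep(c(ft$positive, ft$negative), c(m1, m2))
  out[c(ft$label, ft$feature_names)]
}

#' Apply one of the seven re-balancing cases
#'
#' @inheritParams random_oversample
#' @param case Integer 1-7; see [resampling] for the case definitions.
#' @param smote_k SMOTE neighbourhood size (case 2). Default 5.
#' @param bandwidth_rule Kernel bandwidth rule for the smoothed bootstrap
#'   (cases 3, 5, 7).
#' @return A `rar_resample` object: the re-balanced
#'   [feature_table][as_feature_table], the class counts before and after,
#'   and a per-row provenance flag (`"original"` or `"synthetic"`).
#'   `as_tibble()` renders it with a `.provenance` column.
#' @examples
#' set.seed(2)
#' df <- data.frame(class = rep(c("a", "b"), c(6, 20)),
#'                  x1 = rnorm(26), x2 = rnorm(26))
#' apply_case(df, case = 6, seed = 1)
#' @export
apply_case <- function(data, case, label = "class", positive = NULL,
                       smote_k = 5L, bandwidth_rule = "silverman",
                       seed = NULL) {
  ft <- as_feature_table(data, label, positive)
  sz <- ft_sizes(ft)
  n1 <- sz[["n1"]]; n2 <- sz[["n2"]]; n <- n1 + n2
  if (!case %in% 1:7) abort("`case` must be an integer between 1 and 7.")
  case <- as.integer(case)
  if (case == 1L) {
    return(new_resample(ft, sz, sz, rep("original", n), 1L))
  }
  if (case == 2L) {
    if (2L * n1 > n2) {
      abort("Case 2 needs the majority to be at least twice the minority size.")
    }
    seeds <- with_seed_maybe(seed, sample.int(1e9, 2))
    syn <- smote_generate(ft$X[ft$y == 1L, , drop = FALSE], n1, k = smote_k,
                          seed = seeds[1])
    maj_idx <- which(ft$y == 0L)
    keep_maj <- withr::with_seed(seeds[2], sort(sample(maj_idx, 2L * n1)))
    X <- rbind(ft$X[ft$y == 1L, , drop = FALSE], syn,
               ft$X[keep_maj, , drop = FALSE])
    y <- rep(c(1L, 1L, 0L), c(n1, n1, 2L * n1))
    prov <- rep(c("original", "synthetic", "original"), c(n1, n1, 2L * n1))
    return(new_resample(ft_rebuild(ft, X, y), sz,
                        c(n1 = 2L * n1, n2 = 2L * n1), prov, 2L))
  }
  if (case == 3L) {
    m1 <- floor(n / 2); m2 <- ceiling(n / 2)
    syn <- smoothed_bootstrap(ft, m1 = m1, m2 = m2,
                              bandwidth_rule = bandwidth_rule, seed = seed)
    new_ft <- as_feature_table(as.data.frame(syn), label = ft$label,
                               positive = ft$positive)
    return(new_resample(new_ft, sz, c(n1 = as.integer(m1), n2 = as.integer(m2)),
                        rep("synthetic", n), 3L))
  }
  if (case == 4L) {
    out <- random_oversample(ft, target_n1 = n2, seed = seed)
    out$case <- 4L
    return(out)
  }
  if (case == 5L) {
    syn <- smoothed_bootstrap(ft, m1 = n2 - n1, m2 = 0,
                              bandwidth_rule = bandwidth_rule, seed = seed)
    Xs <- as.matrix(syn[ft$feature_names])
    X <- rbind(ft$X, Xs)
    y <- c(ft$y, rep(1L, n2 - n1))
    prov <- c(rep("original", n), rep("synthetic", n2 - n1))
    return(new_resample(ft_rebuild(ft, X, y), sz, c(n1 = n2, n2 = n2), prov, 5L))
  }
  if (case == 6L) {
    out <- random_undersample(ft, target_n2 = n1, seed = seed)
    out$case <- 6L
    return(out)
  }
  # case 7: replace the majority by n1 smoothed-bootstrap draws from itself
  syn <- smoothed_bootstrap(ft, m1 = 0, m2 = n1,
                            bandwidth_rule = bandwidth_rule, seed = seed)
  Xs <- as.matrix(syn[ft$feature_names])
  X <- rbind(ft$X[ft$y == 1L, , drop = FALSE], Xs)
  y <- rep(c(1L, 0L), c(n1, n1))
  prov <- rep(c("original", "synthetic"), c(n1, n1))
  new_resample(ft_rebuild(ft, X, y), sz, c(n1 = n1, n2 = n1), prov, 7L)
}
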