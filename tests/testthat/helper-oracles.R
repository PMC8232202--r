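# Brute-force reference implementations used as independent oracles.
# These deliberately mirror the definitions (not the package code paths):
# plain loops, explicit threshold walks, exhaustive neighbour scans.

random_table <- function(n1, n2, p, seed, shift = NULL) {
  withr::with_seed(seed, {
    if (is.null(shift)) shift <- runif(p, 0, 2)
    X1 <- matrix(rnorm(n1 * p), n1) + rep(shift, each = n1)
    X2 <- matrix(rnorm(n2 * p), n2)
    df <- as.data.frame(rbind(X1, X2))
    names(df) <- paste0("f", seq_len(p))
    df$class <- rep(c("pos", "neg"), c(n1, n2))
    df
  })
}

table_to_xy <- function(df, label = "class", positive = "pos") {
  X <- as.matrix(df[setdiff(names(df), label)])
  y <- as.integer(df[[label]] == positive)
  list(X = X, y = y)
}

oracle_welch_t <- function(x1, x2) {
  abs(mean(x1) - mean(x2)) / sqrt(var(x1) / length(x1) + var(x2) / length(x2))
}

oracle_fisher <- function(x1, x2) {
  abs(mean(x1) - mean(x2)) / sqrt(var(x1) + var(x2))
}

oracle_hellinger <- function(x1, x2) {
  m1 <- mean(x1); m2 <- mean(x2); v1 <- var(x1); v2 <- var(x2)
  2 - 2 * sqrt(2 * sqrt(v1) * sqrt(v2) / (v1 + v2)) *
    exp(-(m1 - m2)^2 / (4 * (v1 + v2)))
}

# Relief / ReliefF by explicit per-instance neighbour scan
oracle_relief <- function(X, y, k = 1) {
  rng <- apply(X, 2, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1
  Xs <- sweep(sweep(X, 2, rng[1, ]), 2, span, "/")
  n <- nrow(Xs)
  s <- numeric(ncol(Xs))
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(Xs) - Xs[i, ])^2))
    hits <- setdiff(which(y == y[i]), i)
    miss <- which(y != y[i])
    hsel <- hits[order(d[hits], hits)][seq_len(k)]
    msel <- miss[order(d[miss], miss)][seq_len(k)]
    for (h in hsel) s <- s - (Xs[i, ] - Xs[h, ])^2 / k
    for (m in msel) s <- s + (Xs[i, ] - Xs[m, ])^2 / k
  }
  s
}

shannon_ent <- function(y) {
  ps <- as.numeric(table(y)) / length(y)
  -sum(ifelse(ps > 0, ps * log2(ps), 0))
}

oracle_info_gain <- function(x, y) {
  u <- sort(unique(x))
  if (length(u) < 2) return(0)
  thr <- (u[-length(u)] + u[-1]) / 2
  max(vapply(thr, function(t) {
    L <- y[x <= t]; R <- y[x > t]
    shannon_ent(y) - length(L) / length(y) * shannon_ent(L) -
      length(R) / length(y) * shannon_ent(R)
  }, numeric(1)))
}

gini_node <- function(y) {
  ps <- as.numeric(table(y)) / length(y)
  1 - sum(ps^2)
}

oracle_gini_split <- function(x, y) {
  u <- sort(unique(x))
  if (length(u) < 2) return(gini_node(y))
  thr <- (u[-length(u)] + u[-1]) / 2
  min(vapply(thr, function(t) {
    L <- y[x <= t]; R <- y[x > t]
    length(L) / length(y) * gini_node(L) + length(R) / length(y) * gini_node(R)
  }, numeric(1)))
}

oracle_r_value <- function(x, y, k, theta) {
  n <- length(x)
  cnt <- vapply(seq_len(n), function(i) {
    d <- abs(x - x[i])
    d[i] <- Inf
    nb <- order(d, seq_len(n))[seq_len(k)]
    sum(y[nb] != y[i])
  }, numeric(1))
  mean(cnt > theta)
}

oracle_footrule <- function(r1, r2) sum(abs(r1[names(r2)] - r2))

# average precision by an explicit walk over descending score thresholds
oracle_average_precision <- function(scores, pos) {
  thr <- sort(unique(scores), decreasing = TRUE)
  P <- sum(pos)
  rec_prev <- 0
  ap <- 0
  for (t in thr) {
    sel <- scores >= t
    prec <- sum(pos & sel) / sum(sel)
    rec <- sum(pos & sel) / P
    ap <- ap + prec * (rec - rec_prev)
    rec_prev <- rec
  }
  ap
}

random_ranking <- function(feats, seed) {
  withr::with_seed(seed, {
    tibble::tibble(feature = sample(feats), rank = seq_along(feats))
  })
}

score_vector <- function(sv) {
  out <- sv$score
  names(out) <- sv$feature
  out
}
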