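test_that("t statistic matches Welch's test and handles degenerate features", {
  df <- data.frame(class = rep(c("pos", "neg"), each = 3),
                   f1 = c(1, 2, 3, 4, 5, 6),
                   f2 = c(5, 5, 5, 5, 5, 5))
  expect_warning(sv <- score_t_test(df, positive = "pos"), "zero variance")
  tt <- stats::t.test(c(1, 2, 3), c(4, 5, 6))        # independent oracle
  expect_equal(unname(score_vector(sv)["f1"]), abs(unname(tt$statistic)))
  expect_equal(unname(score_vector(sv)["f2"]), 0)    # identical in both classes
  rk <- rank_from_scores(sv)
  expect_equal(rk$feature[rk$rank == 2], "f2")       # degenerate ranked last

  # monotone in the mean gap at equal variance and size
  df2 <- random_table(10, 10, 2, seed = 3, shift = c(3, 0.1))
  rk2 <- rank_from_scores(score_t_test(df2, positive = "pos"))
  expect_equal(rk2$feature[rk2$rank == 1], "f1")
})

test_that("Fisher score follows its closed form", {
  df <- random_table(6, 9, 4, seed = 4)
  xy <- table_to_xy(df)
  sv <- score_vector(score_fisher(df, positive = "pos"))
  for (j in seq_len(4)) {
    expect_equal(unname(sv[j]),
                 oracle_fisher(xy$X[xy$y == 1, j], xy$X[xy$y == 0, j]))
  }
  # identical class distributions score 0
  same <- data.frame(class = rep(c("pos", "neg"), each = 4),
                     f1 = rep(c(1, 2, 3, 4), 2), f2 = rep(c(0, 5, 1, 2), 2))
  expect_equal(unname(score_vector(score_fisher(same, positive = "pos"))),
               c(0, 0))
})

test_that("Hellinger distance is 0 for identical Gaussians and saturates at 2", {
  same <- data.frame(class = rep(c("pos", "neg"), each = 4),
                     f1 = rep(c(1, 2, 3, 4), 2), f2 = rep(c(0, 5, 1, 2), 2))
  expect_equal(unname(score_vector(score_hellinger(same, positive = "pos"))),
               c(0, 0))
  df <- random_table(6, 9, 3, seed = 5)
  xy <- table_to_xy(df)
  sv <- score_vector(score_hellinger(df, positive = "pos"))
  for (j in seq_len(3)) {
    expect_equal(unname(sv[j]),
                 oracle_hellinger(xy$X[xy$y == 1, j], xy$X[xy$y == 0, j]))
  }
  expect_true(all(sv >= 0 & sv <= 2))
  # growing mean gap at fixed variance drives the distance to its cap of 2
  base <- random_table(8, 8, 2, seed = 6, shift = c(0, 0))
  shifted <- base
  shifted$f1[base$class == "pos"] <- shifted$f1[base$class == "pos"] + 100
  expect_gt(score_vector(score_hellinger(shifted, positive = "pos"))["f1"], 1.99)
  const <- data.frame(class = rep(c("pos", "neg"), each = 3),
                      f1 = rep(1, 6), f2 = rnorm(6))
  expect_error(score_hellinger(const, positive = "pos"), "f1")
})

test_that("Relief and ReliefF match an exhaustive neighbour scan", {
  df <- random_table(3, 3, 2, seed = 7)
  xy <- table_to_xy(df)
  expect_equal(unname(score_vector(score_relief(df, positive = "pos"))),
               unname(oracle_relief(xy$X, xy$y, k = 1)))
  df2 <- random_table(5, 7, 3, seed = 8)
  xy2 <- table_to_xy(df2)
  expect_equal(unname(score_vector(score_relieff(df2, positive = "pos",
                                                 k_neighbors = 2))),
               unname(oracle_relief(xy2$X, xy2$y, k = 2)))
  # k = 1 reduces ReliefF to Relief
  expect_equal(score_vector(score_relieff(df2, positive = "pos", k_neighbors = 1)),
               score_vector(score_relief(df2, positive = "pos")))
  # constant feature contributes nothing
  df3 <- df2; df3$f2 <- 1
  expect_equal(unname(score_vector(score_relief(df3, positive = "pos"))["f2"]), 0)
  expect_error(score_relieff(df2, k_neighbors = 0), "at least 1")
})

test_that("information gain and Gini use the best binary split", {
  # perfectly separating threshold on balanced labels: IG = Ent(D) = 1 bit,
  # Gini after split = 0
  df <- data.frame(class = rep(c("pos", "neg"), each = 4),
                   f1 = c(1, 2, 3, 4, 11, 12, 13, 14),
                   f2 = c(1, 7, 3, 9, 2, 8, 4, 10))
  ig <- score_vector(score_info_gain(df, positive = "pos"))
  expect_equal(unname(ig["f1"]), 1)
  gi <- score_vector(score_gini(df, positive = "pos"))
  expect_equal(unname(gi["f1"]), 0)
  # constant feature: no gain, parent impurity kept (0.5 at balance)
  df3 <- df; df3$f2 <- 2
  expect_equal(unname(score_vector(score_info_gain(df3, positive = "pos"))["f2"]), 0)
  expect_equal(unname(score_vector(score_gini(df3, positive = "pos"))["f2"]), 0.5)
  # exhaustive enumeration oracle on random vectors
  for (s in 1:5) {
    df4 <- random_table(4, 6, 2, seed = 20 + s)
    xy <- table_to_xy(df4)
    expect_equal(unname(score_vector(score_info_gain(df4, positive = "pos"))),
                 apply(xy$X, 2, oracle_info_gain, y = xy$y),
                 ignore_attr = TRUE)
    expect_equal(unname(score_vector(score_gini(df4, positive = "pos"))),
                 apply(xy$X, 2, oracle_gini_split, y = xy$y),
                 ignore_attr = TRUE)
  }
})

test_that("R-value counts majority-opposite neighbourhoods", {
  # disjoint well-separated ranges: every neighbourhood is pure, R = 0
  df <- data.frame(class = rep(c("pos", "neg"), c(8, 10)),
                   f1 = c(seq(0, 0.7, length.out = 8), seq(10, 11, length.out = 10)),
                   f2 = rnorm(18))
  sv <- score_vector(score_r_value(df, positive = "pos", k_neighbors = 5))
  expect_equal(unname(sv["f1"]), 0)
  # interleaved labels match the exhaustive scan
  df2 <- random_table(9, 12, 3, seed = 9, shift = c(0.5, 0, 1))
  xy <- table_to_xy(df2)
  sv2 <- score_vector(score_r_value(df2, positive = "pos", k_neighbors = 5))
  expect_equal(unname(sv2), apply(xy$X, 2, oracle_r_value, y = xy$y,
                                  k = 5, theta = 2.5),
               ignore_attr = TRUE)
  # identical point multisets in the two classes: tie rule decides, and the
  # implementation must agree with the oracle that applies the same rule
  df3 <- data.frame(class = rep(c("pos", "neg"), each = 6),
                    f1 = rep(c(1, 2, 3, 4, 5, 6), 2),
                    f2 = rep(c(2, 2, 3, 3, 4, 4), 2))
  xy3 <- table_to_xy(df3)
  sv3 <- score_vector(score_r_value(df3, positive = "pos", k_neighbors = 5))
  expect_equal(unname(sv3), apply(xy3$X, 2, oracle_r_value, y = xy3$y,
                                  k = 5, theta = 2.5),
               ignore_attr = TRUE)
})

test_that("rank_from_scores respects orientation and breaks ties by index", {
  sv <- rarank:::new_scores(c("a", "b", "c"), c(0.2, 0.9, 0.5),
                            "demo", "larger_better")
  expect_equal(rank_from_scores(sv)$feature, c("b", "c", "a"))
  sv2 <- rarank:::new_scores(c("a", "b", "c"), c(0.2, 0.9, 0.5),
                             "demo", "smaller_better")
  expect_equal(rank_from_scores(sv2)$feature, c("a", "c", "b"))
  sv3 <- rarank:::new_scores(c("a", "b", "c"), c(1, 1, 1),
                             "demo", "larger_better")
  expect_equal(rank_from_scores(sv3)$feature, c("a", "b", "c"))
})

test_that("rank_all_filters returns eight full permutations and agrees on a dominant feature", {
  df <- data.frame(class = rep(c("pos", "neg"), each = 10),
                   f1 = c(rnorm(10, 20), rnorm(10)),   # perfect separator
                   f2 = withr::with_seed(10, rnorm(20)))
  rks <- rank_all_filters(df, positive = "pos")
  expect_equal(nrow(rks), 8 * 2)
  split_rk <- split(rks$rank, rks$method)
  expect_true(all(vapply(split_rk, function(r) setequal(r, 1:2), logical(1))))
  first <- vapply(split(rks, rks$method),
                  function(d) d$feature[d$rank == 1], character(1))
  expect_true(all(first == "f1"))
})

test_that("scores are invariant to sample order and to class-label swap", {
  df <- random_table(8, 8, 4, seed = 11)          # balanced so swap is legal
  perm <- withr::with_seed(12, sample(nrow(df)))
  df_perm <- df[perm, ]
  df_swap <- df
  df_swap$class <- ifelse(df$class == "pos", "neg", "pos")
  for (f in list(score_t_test, score_fisher, score_hellinger, score_relief,
                 score_info_gain, score_gini,
                 function(d, positive) score_r_value(d, positive = positive))) {
    base <- score_vector(f(df, positive = "pos"))
    expect_equal(score_vector(f(df_perm, positive = "pos")), base)
    expect_equal(score_vector(f(df_swap, positive = "pos")), base)
  }
})

test_that("larger mean shifts never decrease the separation scores", {
  base <- random_table(30, 30, 2, seed = 13, shift = c(0, 0))
  shifts <- seq(1, 5, by = 0.5)
  get_scores <- function(delta) {
    df <- base
    df$f1[df$class == "pos"] <- df$f1[df$class == "pos"] + delta
    c(t = score_vector(score_t_test(df, positive = "pos"))[["f1"]],
      fisher = score_vector(score_fisher(df, positive = "pos"))[["f1"]],
      hell = score_vector(score_hellinger(df, positive = "pos"))[["f1"]],
      ig = score_vector(score_info_gain(df, positive = "pos"))[["f1"]])
  }
  mat <- vapply(shifts, get_scores, numeric(4))
  for (i in 1:4) expect_true(all(diff(mat[i, ]) >= -1e-10))
})
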