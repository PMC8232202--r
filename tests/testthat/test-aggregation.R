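test_that("Kendall's tau matches its pair-counting definition", {
  a <- tibble::tibble(feature = c("x", "y", "z"), rank = 1:3)
  expect_equal(kendall_tau(a, a), 1)
  rev_a <- tibble::tibble(feature = c("z", "y", "x"), rank = 1:3)
  expect_equal(kendall_tau(a, rev_a), -1)
  b <- tibble::tibble(feature = c("x", "z", "y"), rank = 1:3)
  expect_equal(kendall_tau(a, b), 1 / 3)     # one discordant pair of three
  expect_error(kendall_tau(a, tibble::tibble(feature = c("x", "y", "w"),
                                             rank = 1:3)),
               "different feature sets")
  # symmetry and agreement with the standard estimator on random permutations
  for (s in 1:10) {
    f1 <- random_ranking(letters[1:7], seed = 100 + s)
    f2 <- random_ranking(letters[1:7], seed = 200 + s)
    tau <- kendall_tau(f1, f2)
    expect_equal(tau, kendall_tau(f2, f1))
    r1 <- with(f1, rank[order(feature)])
    r2 <- with(f2, rank[order(feature)])
    expect_equal(tau, unname(stats::cor(r1, r2, method = "kendall")))
  }
})

test_that("footrule distance is a metric on permutations", {
  a <- tibble::tibble(feature = c("a", "b", "c"), rank = 1:3)
  b <- tibble::tibble(feature = c("c", "b", "a"), rank = 1:3)
  expect_equal(footrule_distance(a, a), 0)
  expect_equal(footrule_distance(a, b), 4)
  for (s in 1:100) {
    x <- random_ranking(letters[1:6], seed = 300 + s)
    y <- random_ranking(letters[1:6], seed = 400 + s)
    z <- random_ranking(letters[1:6], seed = 500 + s)
    expect_equal(footrule_distance(x, y), footrule_distance(y, x))
    expect_lte(footrule_distance(x, y),
               footrule_distance(x, z) + footrule_distance(z, y))
  }
  # the score-weighted variant reduces to the plain one for unit score steps
  expect_equal(footrule_distance(a, b, rank_scores = c(3, 2, 1)), 8)
})

test_that("exhaustive aggregation finds the global footrule minimiser", {
  feats <- letters[1:5]
  same <- random_ranking(feats, seed = 1)
  agg0 <- aggregate_brute_force(list(same, same, same))
  expect_equal(agg0$objective, 0)
  expect_equal(agg0$ranking$feature, same$feature)
  for (s in 1:20) {
    lists <- lapply(1:3, function(i) random_ranking(feats, seed = 600 + 10 * s + i))
    agg <- aggregate_brute_force(lists)
    # verify optimality independently over all 120 permutations
    perms <- rarank:::permutations_lex(5)
    objs <- apply(perms, 1, function(pm) {
      delta <- tibble::tibble(feature = feats[pm], rank = 1:5)
      mean(vapply(lists, function(f) footrule_distance(delta, f), numeric(1)))
    })
    expect_equal(agg$objective, min(objs))
  }
  # symmetric in two equally weighted lists
  l1 <- random_ranking(feats, seed = 31)
  l2 <- random_ranking(feats, seed = 32)
  expect_equal(aggregate_brute_force(list(l1, l2))$objective,
               aggregate_brute_force(list(l2, l1))$objective)
  expect_error(aggregate_brute_force(lapply(1:2, function(i)
    random_ranking(letters[1:9], seed = i))), "aggregate_ce")
})

test_that("cross-entropy search is seeded, monotone and exact on easy problems", {
  feats <- letters[1:5]
  same <- random_ranking(feats, seed = 2)
  agg <- aggregate_ce(list(same, same, same), seed = 1)
  expect_equal(agg$objective, 0)
  expect_lte(agg$iterations, 2)
  expect_equal(agg$ranking$feature, same$feature)
  lists <- lapply(1:4, function(i) random_ranking(feats, seed = 700 + i))
  a1 <- aggregate_ce(lists, seed = 99)
  a2 <- aggregate_ce(lists, seed = 99)
  expect_identical(a1$ranking, a2$ranking)
  expect_identical(a1$trace, a2$trace)
  expect_true(all(diff(a1$trace) <= 0))
  # never below the exact optimum
  expect_gte(a1$objective, aggregate_brute_force(lists)$objective)
})

test_that("aggregation is equivariant under feature relabeling", {
  feats <- letters[1:6]
  relab <- c(a = "T4", b = "Q1", c = "Z9", d = "M2", e = "K7", f = "W5")
  lists <- lapply(1:5, function(i) random_ranking(feats, seed = 800 + i))
  lists_r <- lapply(lists, function(f) {
    tibble::tibble(feature = unname(relab[f$feature]), rank = f$rank)
  })
  agg <- aggregate_ce(lists, seed = 5)
  agg_r <- aggregate_ce(lists_r, seed = 5)
  expect_equal(unname(relab[agg$ranking$feature]), agg_r$ranking$feature)
  expect_equal(agg$objective, agg_r$objective)
})

test_that("mean pairwise tau averages all unordered pairs", {
  f1 <- tibble::tibble(feature = c("a", "b", "c"), rank = 1:3)
  f3 <- tibble::tibble(feature = c("a", "c", "b"), rank = 1:3)
  expect_equal(mean_pairwise_tau(list(f1, f1, f1)), 1)
  # pairwise taus (1, 1/3, 1/3) average to 5/9
  expect_equal(mean_pairwise_tau(list(f1, f1, f3)), 5 / 9)
  lists8 <- lapply(1:8, function(i) random_ranking(letters[1:5], seed = 900 + i))
  taus <- combn(8, 2, function(ij) kendall_tau(lists8[[ij[1]]], lists8[[ij[2]]]))
  expect_length(taus, 28)
  expect_equal(mean_pairwise_tau(lists8), mean(taus))
})
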