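make_imbalanced <- function(n1, n2, p = 3, seed = 50) {
  random_table(n1, n2, p, seed = seed)
}

test_that("random over-sampling duplicates only original minority rows", {
  df <- make_imbalanced(8, 21)
  ft <- as_feature_table(df)
  expect_identical(random_oversample(ft, target_n1 = 8)$table$X, ft$X)
  res <- random_oversample(ft, target_n1 = 21, seed = 1)
  expect_equal(unname(rarank:::ft_sizes(res$table)), c(21, 21))
  expect_equal(sum(res$provenance == "synthetic"), 13)
  syn <- res$table$X[res$provenance == "synthetic", , drop = FALSE]
  orig_min <- ft$X[ft$y == 1, , drop = FALSE]
  for (i in seq_len(nrow(syn))) {
    expect_true(any(apply(orig_min, 1, identical, y = syn[i, ])))
  }
  expect_error(random_oversample(ft, target_n1 = 5), "below the current")
})

test_that("random under-sampling keeps a subset of original majority rows", {
  df <- make_imbalanced(31, 73)
  ft <- as_feature_table(df)
  expect_identical(random_undersample(ft, target_n2 = 73)$table$X, ft$X)
  res <- random_undersample(ft, target_n2 = 31, seed = 2)
  expect_equal(unname(rarank:::ft_sizes(res$table)), c(31, 31))
  kept <- res$table$X[res$table$y == 0, , drop = FALSE]
  orig_maj <- ft$X[ft$y == 0, , drop = FALSE]
  expect_true(all(apply(kept, 1, function(r)
    any(apply(orig_maj, 1, identical, y = r)))))
  expect_error(random_undersample(ft, target_n2 = 100), "exceeds")
})

test_that("SMOTE points lie on the segment between seed and neighbour", {
  X <- as.matrix(make_imbalanced(10, 12)[1:10, paste0("f", 1:3)])
  syn <- smote_generate(X, n_new = 40, k = 5, seed = 3)
  expect_equal(dim(syn), c(40, 3))
  # each synthetic point must be xi + u (xih - xi) for some pair (xi, xih)
  on_segment <- apply(syn, 1, function(z) {
    for (i in seq_len(nrow(X))) {
      for (h in seq_len(nrow(X))[-i]) {
        dir <- X[h, ] - X[i, ]
        rel <- z - X[i, ]
        u <- sum(rel * dir) / sum(dir * dir)
        if (u >= -1e-9 && u <= 1 + 1e-9 &&
            sqrt(sum((rel - u * dir)^2)) < 1e-8) return(TRUE)
      }
    }
    FALSE
  })
  expect_true(all(on_segment))
  expect_identical(smote_generate(X, 7, seed = 9), smote_generate(X, 7, seed = 9))
  expect_equal(nrow(smote_generate(X, 0)), 0)
  expect_error(smote_generate(X, -1), "nonnegative")
  expect_error(smote_generate(X[1, , drop = FALSE], 3), "at least 2")
})

test_that("smoothed bootstrap honours counts and degenerates to plain bootstrap", {
  df <- make_imbalanced(10, 15)
  syn <- smoothed_bootstrap(df, m1 = 12, m2 = 7, seed = 4)
  expect_equal(sum(syn$class == "pos"), 12)
  expect_equal(sum(syn$class == "neg"), 7)
  # zero-bandwidth limit reproduces original rows exactly
  syn0 <- smoothed_bootstrap(df, m1 = 20, m2 = 0, bandwidth_scale = 0, seed = 5)
  orig_min <- as.matrix(df[df$class == "pos", paste0("f", 1:3)])
  Z <- as.matrix(syn0[paste0("f", 1:3)])
  expect_true(all(apply(Z, 1, function(r)
    any(apply(orig_min, 1, function(o) all(abs(o - r) < 1e-12))))))
})

test_that("the seven cases hit their exact target class sizes", {
  df <- make_imbalanced(16, 51)
  ft <- as_feature_table(df)
  # case 1 passes the table through untouched
  r1 <- apply_case(ft, 1)
  expect_identical(r1$table$X, ft$X)
  expect_true(all(r1$provenance == "original"))

  expect_equal(unname(rarank:::ft_sizes(apply_case(ft, 2, seed = 6)$table)),
               c(32, 32))
  expect_equal(unname(rarank:::ft_sizes(apply_case(ft, 3, seed = 6)$table)),
               c(33, 34))
  r4 <- apply_case(as_feature_table(make_imbalanced(21, 51, seed = 51)), 4,
                   seed = 6)
  expect_equal(unname(rarank:::ft_sizes(r4$table)), c(51, 51))
  expect_equal(unname(rarank:::ft_sizes(apply_case(ft, 5, seed = 6)$table)),
               c(51, 51))
  expect_equal(unname(rarank:::ft_sizes(apply_case(ft, 6, seed = 6)$table)),
               c(16, 16))
  expect_equal(unname(rarank:::ft_sizes(apply_case(ft, 7, seed = 6)$table)),
               c(16, 16))
  expect_error(apply_case(ft, 8), "between 1 and 7")

  # case-4 synthetic rows are copies of original minority rows
  syn4 <- r4$table$X[r4$provenance == "synthetic", , drop = FALSE]
  orig4 <- as.matrix(make_imbalanced(21, 51, seed = 51)[1:21, paste0("f", 1:3)])
  expect_true(all(apply(syn4, 1, function(r)
    any(apply(orig4, 1, identical, y = r)))))
})

test_that("original rows survive bit-identical and provenance partitions correctly", {
  df <- make_imbalanced(12, 30)
  ft <- as_feature_table(df)
  for (case in c(2, 5, 7)) {
    res <- apply_case(ft, case, seed = 7)
    expect_true(all(res$provenance %in% c("original", "synthetic")))
    orig_rows <- res$table$X[res$provenance == "original", , drop = FALSE]
    expect_true(all(apply(orig_rows, 1, function(r)
      any(apply(ft$X, 1, identical, y = r)))))
  }
  res3 <- apply_case(ft, 3, seed = 7)
  expect_true(all(res3$provenance == "synthetic"))
})

test_that("resampling is reproducible bit-for-bit from the seed", {
  df <- make_imbalanced(9, 25)
  for (case in 2:7) {
    a <- apply_case(df, case, seed = 11)
    b <- apply_case(df, case, seed = 11)
    expect_identical(a$table$X, b$table$X)
    expect_identical(a$provenance, b$provenance)
  }
})
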