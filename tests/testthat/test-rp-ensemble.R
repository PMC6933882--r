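test_that("random projections have unit-norm columns and honour seeds", {
  for (kind in c("gaussian_sphere", "bernoulli_pm1")) {
    R <- sample_projection(4, 12, kind, seed = 3)$matrix
    expect_equal(dim(R), c(4L, 12L))
    expect_equal(sqrt(colSums(R^2)), rep(1, 12), tolerance = 1e-9)
  }
  B <- sample_projection(4, 12, "bernoulli_pm1", seed = 3)$matrix
  expect_true(all(abs(abs(B) - 1 / 2) < 1e-12))  # entries +/- 1/sqrt(q)
  expect_identical(sample_projection(4, 12, "gaussian_sphere", seed = 5)$matrix,
                   sample_projection(4, 12, "gaussian_sphere", seed = 5)$matrix)
  expect_false(identical(sample_projection(4, 12, seed = 5)$matrix,
                         sample_projection(4, 12, seed = 6)$matrix))
  expect_error(sample_projection(12, 12), "q < n")
})

test_that("projection is the linear map by the sampled matrix", {
  pr <- sample_projection(2, 3, "gaussian_sphere", seed = 1)
  pr$matrix <- matrix(c(1, 0, 0, 1, 2, -1), 2, 3)  # hand-written R
  X <- matrix(c(1, 4, 2, 5, 3, 6), 2, 3)
  expect_equal(project(pr, X), X %*% t(pr$matrix))
  expect_equal(as.numeric(project(pr, c(0, 0, 0))), c(0, 0))
  x <- c(1, 2, 3); y <- c(-1, 0, 2)
  expect_equal(project(pr, 2 * x + 3 * y),
               2 * project(pr, x) + 3 * project(pr, y))
  expect_error(project(pr, matrix(0, 2, 4)), "width")
})

test_that("leave-one-out kNN error matches the brute-force oracle exhaustively", {
  # separated clusters and constant labels are error-free
  well <- rbind(matrix(0.01 * rnorm(10), 5, 2) + 10,
                matrix(0.01 * rnorm(10), 5, 2) - 10)
  expect_equal(loo_knn_error(well, rep(c(1, 0), each = 5), 1), 0)
  expect_equal(loo_knn_error(matrix(rnorm(12), 6, 2), rep(1, 6), 3), 0)

  # interleaved 1-D labels, k = 3, against the O(N^2) oracle
  x <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 1)
  y <- c(1, 0, 1, 0, 1, 0)
  expect_equal(loo_knn_error(x, y, 3), loo_knn_oracle(x, y, 3))

  # random instances with N <= 12, duplicated points to force distance ties
  set.seed(13)
  for (rep in 1:20) {
    N <- sample(4:12, 1)
    X <- matrix(sample(0:3, N * 2, replace = TRUE), N, 2)  # many exact ties
    y <- sample(c(0L, 1L), N, replace = TRUE)
    if (length(unique(y)) < 2) y[1] <- 1L - y[1]
    for (k in unique(pmin(c(1, 3, N - 1), N - 1)))
      expect_equal(loo_knn_error(X, y, k), loo_knn_oracle(X, y, k))
  }
  expect_error(loo_knn_error(matrix(0, 3, 2), c(1, 0, 1), 3), "k must")
})

test_that("fitted blocks store the argmin of their candidate errors", {
  s <- separable_set(15, dim = 10, gap = 1.2)
  model <- rp_fit(s$X, s$y, B1 = 4, B2 = 6, q = 3, seed = 17)
  for (b in model$blocks) {
    expect_true(b$k %in% model$k_grid)
    expect_gte(b$loo_error, 0); expect_lte(b$loo_error, 1)
  }
  # re-derive every candidate error of block 1 and check none beats the pick
  projections <- sippred:::.with_seed(17, lapply(1:24, function(i)
    sample_projection(3, 10, "gaussian_sphere")))
  errs <- unlist(lapply(projections[1:6], function(pr) {
    vapply(model$k_grid, function(k)
      loo_knn_error(project(pr, s$X), s$y, k), numeric(1))
  }))
  expect_equal(model$blocks[[1]]$loo_error, min(errs))
})

test_that("degenerate single-block single-candidate ensemble is a plain kNN", {
  s <- separable_set(10, dim = 8, gap = 4)
  model <- rp_fit(s$X, s$y, B1 = 1, B2 = 1, q = 2, seed = 23)
  fr <- vote_fraction(model, s$X)
  expect_true(all(fr %in% c(0, 1)))
  b <- model$blocks[[1]]
  proj <- project(b$projection, s$X)
  manual <- vapply(seq_len(nrow(proj)), function(i) {
    d <- colSums((t(b$train) - proj[i, ])^2)
    nb <- order(d, seq_along(d))[seq_len(b$k)]
    as.integer(2 * sum(s$y[nb]) >= b$k)
  }, integer(1))
  expect_equal(as.integer(fr), manual)
})

test_that("separable training data is perfectly re-predicted by the ensemble", {
  s <- separable_set(30, dim = 20, gap = 6)
  model <- rp_fit(s$X, s$y, B1 = 10, B2 = 5, q = 5, seed = 29)
  expect_equal(predict(model, s$X), s$y)
  expect_equal(vote_fraction(model, s$X), as.numeric(s$y))
  # ensemble training error no worse than the worst single block's LOO error
  worst <- max(vapply(model$blocks, `[[`, numeric(1), "loo_error"))
  expect_lte(mean(predict(model, s$X) != s$y), worst)
})

test_that("vote fractions are multiples of 1/B1 and threshold equals the prior", {
  set.seed(31)
  X <- matrix(rnorm(36 * 6), 36, 6)
  y <- rep(c(1L, 0L, 0L), 12)  # prior 1/3
  model <- rp_fit(X, y, B1 = 6, B2 = 4, q = 2, seed = 31)
  expect_equal(model$vote_threshold, 1 / 3)
  new <- matrix(rnorm(10 * 6), 10, 6)
  fr <- vote_fraction(model, new)
  expect_true(all(abs(fr * 6 - round(fr * 6)) < 1e-12))
  # a fraction exactly at the threshold is called positive (>= rule)
  model$vote_threshold <- fr[1]
  expect_equal(predict(model, new)[1], 1L)
})

test_that("hand-built three-block model votes per manual kNN tally", {
  s <- separable_set(6, dim = 5, gap = 2, seed = 37)
  model <- rp_fit(s$X, s$y, B1 = 3, B2 = 2, q = 2, seed = 37)
  new <- matrix(rnorm(4 * 5), 4, 5)
  manual <- rowMeans(vapply(model$blocks, function(b) {
    proj <- project(b$projection, new)
    vapply(seq_len(4), function(i) {
      d <- colSums((t(b$train) - proj[i, ])^2)
      nb <- order(d, seq_along(d))[seq_len(b$k)]
      as.integer(2 * sum(s$y[nb]) >= b$k)
    }, integer(1))
  }, integer(4)))
  expect_equal(vote_fraction(model, new), manual)
})

test_that("identical seeds give identical models and predictions", {
  s <- separable_set(12, dim = 8, gap = 1)
  m1 <- rp_fit(s$X, s$y, B1 = 3, B2 = 4, q = 3, seed = 41)
  m2 <- rp_fit(s$X, s$y, B1 = 3, B2 = 4, q = 3, seed = 41)
  expect_identical(m1$blocks, m2$blocks)
  new <- matrix(rnorm(5 * 8), 5, 8)
  expect_identical(predict(m1, new), predict(m2, new))
})

test_that("lowering the vote threshold never shrinks the positive set", {
  set.seed(43)
  X <- matrix(rnorm(40 * 10), 40, 10)
  y <- rep(c(1L, 0L), each = 20)
  model <- rp_fit(X, y, B1 = 5, B2 = 4, q = 3, seed = 43)
  new <- matrix(rnorm(30 * 10), 30, 10)
  fr <- vote_fraction(model, new)
  counts <- vapply(seq(1, 0, by = -0.1), function(th) sum(fr >= th), integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("imbalanced 1:11 training data sets the documented low threshold", {
  set.seed(47)
  X <- matrix(rnorm(120 * 8), 120, 8)
  y <- rep(c(1L, 0L), c(10, 110))
  X[y == 1, ] <- X[y == 1, ] + 1.5
  model <- rp_fit(X, y, B1 = 10, B2 = 3, q = 3, seed = 47)
  expect_equal(model$vote_threshold, 10 / 120)
  # weak vote support (1 block in 10) already flags a positive
  fr <- vote_fraction(model, X)
  expect_true(all((fr >= 10 / 120) == (predict(model, X) == 1L)))
})

test_that("fit rejects invalid inputs", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(rp_fit(X, rep(1L, 10)), "both classes")
  expect_error(rp_fit(X, rep(c(1L, 0L), 5), q = 2), "q < n")
  expect_error(vote_fraction(rp_fit(X, rep(c(1L, 0L), 5), B1 = 1, B2 = 1, q = 1),
                             matrix(0, 1, 3)), "width")
})
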