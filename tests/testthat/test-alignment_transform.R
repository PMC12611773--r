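test_that("apply_transform maps rows through W x + b", {
  X <- withr::with_seed(1, matrix(rnorm(40), 8, 5))
  id <- affine_transform(diag(5))
  expect_equal(apply_transform(id, X), X)
  ## W = 2I scales all dot products by 4
  two <- affine_transform(2 * diag(5))
  t1 <- sample_random_triplets(8, 10, seed = 2)
  expect_equal(pair_similarities(apply_transform(two, X), t1),
               4 * pair_similarities(X, t1))
  ## row-wise matrix-vector oracle
  tr <- random_affine(5, seed = 3)
  Y <- apply_transform(tr, X)
  for (r in seq_len(nrow(X)))
    expect_equal(Y[r, ], as.numeric(tr$W %*% X[r, ] + tr$b))
  expect_error(apply_transform(tr, X[, 1:3]), "columns")
})

test_that("hard_align_loss is the mean negative log softmax likelihood", {
  expect_equal(hard_align_loss(c(0, 0, 0), 1L), log(3))
  ## chosen pair dominates -> loss -> 0
  expect_lt(hard_align_loss(c(60, 0, 0), 1L), 1e-20)
  ## independent per-triplet log-softmax oracle
  S <- withr::with_seed(4, matrix(rnorm(150), ncol = 3))
  ch <- withr::with_seed(5, sample(1:3, 50, TRUE))
  want <- -mean(vapply(seq_len(50), function(s)
    log(softmax_oracle(S[s, ])[ch[s]]), numeric(1)))
  expect_equal(hard_align_loss(S, ch), want, tolerance = 1e-9)
})

test_that("soft_align_loss is mean KL(p* || q) and reduces to hard on one-hot", {
  ## q = p* -> 0
  S <- withr::with_seed(6, matrix(rnorm(90), ncol = 3))
  q <- choice_probabilities(S)
  expect_equal(soft_align_loss(S, q), 0, tolerance = 1e-12)
  ## one-hot target, equal sims -> ln 3
  expect_equal(soft_align_loss(c(1, 1, 1), c(1, 0, 0)), log(3))
  ## non-negativity sweep (Gibbs' inequality)
  P <- random_soft(1000, seed = 7)
  S2 <- withr::with_seed(8, matrix(rnorm(3000), ncol = 3))
  expect_gte(soft_align_loss(S2, P), 0)
  for (s in c(1, 500, 1000))
    expect_gte(soft_align_loss(S2[s, ], P[s, ]), 0)
  ## one-hot targets: identical to hard_align_loss
  ch <- withr::with_seed(9, sample(1:3, 30, TRUE))
  onehot <- matrix(0, 30, 3)
  onehot[cbind(1:30, ch)] <- 1
  S3 <- withr::with_seed(10, matrix(rnorm(90), ncol = 3))
  expect_equal(soft_align_loss(S3, onehot), hard_align_loss(S3, ch),
               tolerance = 1e-12)
})

test_that("transform_regularizer vanishes on scaled identities and ignores cI shifts", {
  for (c0 in withr::with_seed(11, rnorm(20, sd = 3)))
    expect_equal(transform_regularizer(c0 * diag(4), 1), 0)
  expect_equal(transform_regularizer(diag(c(1, 3)), 1), 2.0)
  W <- withr::with_seed(12, matrix(rnorm(36), 6, 6))
  for (c0 in c(-2.5, 0.1, 7))
    expect_equal(transform_regularizer(W + c0 * diag(6), 1.3),
                 transform_regularizer(W, 1.3), tolerance = 1e-9)
  expect_error(transform_regularizer(matrix(1, 2, 3)), "square")
})

test_that("fit_transform recovers a known affine target map", {
  set.seed(11)
  m <- 120; p <- 12
  X <- matrix(rnorm(m * p), m, p)
  truth <- random_affine(p, seed = 21)
  Xt <- apply_transform(truth, X)
  trips <- sample_random_triplets(m, 3000, seed = 2)
  soft <- choice_probabilities(pair_similarities(Xt, trips))
  resp <- triplet_responses(trips, soft = soft)
  fit <- fit_transform(X, resp, lambda_reg = 1e-3, learning_rate = 0.02,
                       epochs = 30, batch_size = 256, seed = 3)
  hold <- sample_random_triplets(m, 1200, seed = 4)
  ref <- choose_odd_one_out(pair_similarities(Xt, hold))$pair
  got <- choose_odd_one_out(pair_similarities(apply_transform(fit, X), hold))$pair
  expect_gte(mean(ref == got), 0.95)
  ## objective decreases from start to end; no epoch jumps beyond tolerance
  h <- attr(fit, "history")
  expect_lt(h[length(h)], h[1])
  expect_lt(max(diff(h)), 0.02)
  ## determinism
  fit2 <- fit_transform(X, resp, lambda_reg = 1e-3, learning_rate = 0.02,
                        epochs = 30, batch_size = 256, seed = 3)
  expect_identical(fit$W, fit2$W)
})

test_that("self-distillation targets keep W at a scaled identity", {
  set.seed(13)
  m <- 60; p <- 8
  X <- matrix(rnorm(m * p), m, p)
  trips <- sample_random_triplets(m, 1500, seed = 5)
  soft <- choice_probabilities(pair_similarities(X, trips))
  fit <- fit_transform(X, triplet_responses(trips, soft = soft),
                       lambda_reg = 1e-3, epochs = 10, seed = 6)
  mu <- mean(diag(fit$W))
  expect_lt(sqrt(sum((fit$W - diag(mu, p))^2)), 0.1 * p)
  h <- attr(fit, "history")
  expect_lte(h[length(h)], h[1] + 1e-8)
  ## nearest-neighbour preservation under the fitted transform
  S0 <- X %*% t(X); diag(S0) <- -Inf
  Xf <- apply_transform(fit, X)
  S1 <- Xf %*% t(Xf); diag(S1) <- -Inf
  expect_gte(mean(max.col(S0, "first") == max.col(S1, "first")), 0.9)
})

test_that("identity deviation shrinks along the lambda grid", {
  set.seed(14)
  m <- 80; p <- 10
  X <- matrix(rnorm(m * p), m, p)
  truth <- random_affine(p, seed = 22)
  trips <- sample_random_triplets(m, 1500, seed = 7)
  soft <- choice_probabilities(pair_similarities(apply_transform(truth, X), trips))
  resp <- triplet_responses(trips, soft = soft)
  devs <- vapply(c(1e-3, 1e-1, 1e1), function(l) {
    f <- fit_transform(X, resp, lambda_reg = l, learning_rate = 0.02,
                       epochs = 12, batch_size = 256, seed = 3)
    mu <- mean(diag(f$W))
    sqrt(sum((f$W - diag(mu, p))^2))
  }, numeric(1))
  expect_true(all(diff(devs) < 0))
  expect_error(fit_transform(X, resp, lambda_reg = -1), "lambda_reg")
})
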