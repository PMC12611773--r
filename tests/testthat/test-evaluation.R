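test_that("rsm kernels: pearson equals cosine of centred rows, diagonal 1", {
  X <- withr::with_seed(1, matrix(rnorm(80), 10, 8))
  X[2, ] <- X[1, ]
  rp <- rsm(X, "pearson")
  rc <- rsm(X, "cosine")
  expect_equal(rp$matrix[1, 2], 1)
  expect_equal(rc$matrix[1, 2], 1)
  expect_equal(diag(rp$matrix), rep(1, 10))
  ## antipodal rows
  Y <- rbind(X[3, ], -X[3, ], X[4, ])
  expect_equal(rsm(Y, "cosine")$matrix[1, 2], -1)
  ## algebraic equivalence to cosine of explicitly centred rows
  Xc <- X - rowMeans(X)
  expect_equal(rp$matrix, rsm(Xc, "cosine")$matrix, tolerance = 1e-12)
  ## constant row rejected by name under pearson
  Xbad <- X; Xbad[5, ] <- 2
  expect_error(rsm(Xbad, "pearson"), "5")
})

test_that("rsa_spearman compares strictly-upper triangles with rank invariance", {
  X <- withr::with_seed(2, matrix(rnorm(200), 20, 10))
  a <- rsm(X, "pearson")
  expect_equal(rsa_spearman(a, a), 1.0)
  ## strictly monotone transform of the entries -> still 1
  b <- a; b$matrix <- tanh(3 * a$matrix)
  expect_equal(rsa_spearman(a, b), 1.0)
  ## symmetry
  r1 <- withr::with_seed(3, matrix(rnorm(10000), 100))
  r2 <- withr::with_seed(4, matrix(rnorm(10000), 100))
  r1 <- (r1 + t(r1)) / 2; r2 <- (r2 + t(r2)) / 2
  expect_equal(rsa_spearman(r1, r2), rsa_spearman(r2, r1))
  expect_lt(abs(rsa_spearman(r1, r2)), 0.1)
  expect_error(rsa_spearman(r1, r2[1:50, 1:50]), "dimensions")
})

test_that("majority_response takes the mode with seeded uniform tie-break", {
  expect_equal(majority_response(c(3, 1, 1)), 1L)
  expect_equal(majority_response(c(0, 0, 5)), 3L)
  picks <- vapply(1:400, function(s) majority_response(c(2, 2, 1), seed = s),
                  numeric(1))
  expect_true(all(picks %in% 1:2))
  expect_lt(abs(mean(picks == 1) - 0.5), 0.1)
  expect_error(majority_response(c(0, 0, 0)), "at least 1")
})

test_that("noise_ceiling_loo matches its closed-form extremes", {
  trips <- sample_random_triplets(10, 40, seed = 1)
  unan <- triplet_responses(trips, choice = rep(rep(1L, 40), 4),
                            triplet = rep(1:40, 4))
  expect_equal(noise_ceiling_loo(unan), 1.0)
  ## two raters who always disagree -> 0
  disagree <- triplet_responses(trips, choice = c(rep(1L, 40), rep(2L, 40)),
                                triplet = rep(1:40, 2))
  expect_equal(noise_ceiling_loo(disagree), 0.0)
  ## uniform raters, 5 per triplet -> about 1/3
  trips2 <- sample_random_triplets(30, 400, seed = 2)
  ch <- withr::with_seed(3, sample(1:3, 2000, TRUE))
  unif <- triplet_responses(trips2, choice = ch, triplet = rep(1:400, 5))
  nc <- noise_ceiling_loo(unif, seed = 4)
  se <- sqrt(2 / 9 / 400)
  expect_lt(abs(nc - 1 / 3), 2 * se + 0.02)
  ## single-response triplets are excluded with a warning
  solo <- triplet_responses(trips, choice = c(1L, 1L, 2L),
                            triplet = c(1L, 1L, 2L))
  expect_warning(nc2 <- noise_ceiling_loo(solo), "single response")
  expect_equal(nc2, 1.0)
})

test_that("RT preprocessing and participant exclusion apply the stated rules", {
  pre <- preprocess_rts(c(1.0, 12.0, 10.0, 0.2))
  expect_equal(pre$log_rt[1], 0)
  expect_equal(pre$keep, c(TRUE, FALSE, TRUE, TRUE))  # strict > 10 s; no lower bound
  expect_error(preprocess_rts(c(1, -2)), "positive")
  df <- data.frame(participant = 1:4,
                   catch_accuracy = c(0.95, 0.89, 1.0, 0.90),
                   n_missing = c(2, 0, 11, 10))
  kept <- exclude_participants(df)
  expect_equal(kept$participant, c(1L, 4L))
  df$catch_accuracy[1] <- 1.2
  expect_error(exclude_participants(df), "\\[0, 1\\]")
})

test_that("entropy-RT correlation recovers the simulated coupling", {
  h <- seq(0, log(3), length.out = 50)
  expect_equal(entropy_rt_correlation(h, exp(2 * h)), 1.0)
  ## end-to-end: annotators with positive RT slope
  ## spreads chosen so triplet entropies vary over (0, ln 3) rather than
  ## saturating at 0; a near-constant entropy has no rank signal to recover
  sp <- generate_hierarchy(3, 2, 4, 8, c(1.5, 0.8, 0.4), seed = 5)
  an <- annotator_model(temperature = 1, lapse_rate = 0, rt_intercept = 0.3,
                        rt_slope = 0.8, rt_noise_sd = 0.1)
  trips <- sample_random_triplets(24, 400, seed = 6)
  resp <- simulate_responses(sp, trips, an, 5, seed = 7)
  ment <- triplet_entropy(
    choice_probabilities(pair_similarities(sp$embeddings, trips)))
  mlrt <- tapply(log(resp$rt_seconds), resp$triplet, mean)
  rho <- entropy_rt_correlation(ment, as.numeric(mlrt))
  expect_gt(rho, 0.4)
  ## permutation null: shuffled pairing near 0
  rho0 <- entropy_rt_correlation(ment, withr::with_seed(8, sample(mlrt)))
  expect_lt(abs(rho0), 0.2)
})

test_that("distance_change_by_level is zero for identical and scaled checkpoints", {
  sp <- small_space()
  out0 <- distance_change_by_level(sp$embeddings, sp$embeddings, sp$labels)
  expect_true(all(abs(out0$mean_z_change) < 1e-12))
  out2 <- distance_change_by_level(sp$embeddings, 2 * sp$embeddings, sp$labels)
  expect_true(all(abs(out2$mean_z_change) < 1e-9))
  ## rotation invariance of either checkpoint
  Q <- qr.Q(qr(withr::with_seed(9, matrix(rnorm(64), 8, 8))))
  pert <- sp$embeddings + withr::with_seed(10, matrix(rnorm(96, sd = 0.3), 12, 8))
  a <- distance_change_by_level(sp$embeddings, pert, sp$labels)
  b <- distance_change_by_level(sp$embeddings %*% Q, pert, sp$labels)
  expect_equal(a$mean_z_change, b$mean_z_change, tolerance = 1e-9)
  expect_error(distance_change_by_level(sp$embeddings, pert[1:5, ], sp$labels),
               "different item sets")
})

test_that("distillation pulls same-category items together in z-distance terms", {
  sp <- generate_hierarchy(3, 2, 5, 8, c(6, 1.5, 0.8), seed = 11)
  X <- sp$embeddings
  ## teacher: sharpened hierarchy (items shrunk toward basic centroids)
  cent <- apply(X, 2, function(col) ave(col, sp$labels$basic))
  teacher <- 0.3 * X + 0.7 * cent
  ds <- pseudolabel(teacher, sample_random_triplets(nrow(X), 2500, seed = 12))
  st <- student_encoder("linear", 8, 8, init_scale = 0.25, seed = 13)
  tuned <- distill(st, ds, X, tau_student = 1, epochs = 30,
                   learning_rate = 0.02, seed = 14)
  out <- distance_change_by_level(encode(st, X), encode(tuned, X), sp$labels)
  z <- setNames(out$mean_z_change, out$relation_level)
  ## generator leaves coincide with basic cells, so within-category pairs
  ## are classified same_subordinate here
  expect_lt(z[["same_subordinate"]], 0)
  expect_gt(z[["different_superordinate"]], 0)
})

test_that("relation levels are classified from the nested label triple", {
  labels <- data.frame(
    item = 1:6,
    subordinate = c(1, 1, 2, 3, 4, 5),
    basic = c(1, 1, 1, 2, 3, 4),
    superordinate = c(1, 1, 1, 1, 2, 2))
  X0 <- withr::with_seed(20, matrix(rnorm(24), 6, 4))
  X1 <- X0 + withr::with_seed(21, matrix(rnorm(24, sd = 0.2), 6, 4))
  out <- distance_change_by_level(X0, X1, labels)
  want <- c(same_subordinate = 1L,      # (1,2)
            same_basic = 2L,            # (1,3), (2,3)
            same_superordinate = 4L,    # (1,4), (2,4), (3,4), (5,6)
            different_superordinate = 8L)
  expect_equal(setNames(out$n_pairs, out$relation_level), want)
})

test_that("bootstrap_ci gives percentile CIs with stated coverage", {
  expect_equal(bootstrap_ci(rep(0.7, 50), 20, 100, seed = 1),
               list(mean = 0.7, lo95 = 0.7, hi95 = 0.7))
  ci <- bootstrap_ci(c(0, 1, 1, 0), 100, 1000, seed = 2)
  expect_identical(ci, bootstrap_ci(c(0, 1, 1, 0), 100, 1000, seed = 2))
  ## coverage of the true mean 0.5 for Bernoulli scores
  cover <- vapply(1:200, function(rep) {
    x <- withr::with_seed(1000 + rep, rbinom(1000, 1, 0.5))
    ci <- bootstrap_ci(x, 100, 1000, seed = rep)
    ci$lo95 <= 0.5 && 0.5 <= ci$hi95
  }, logical(1))
  expect_gt(mean(cover), 0.88)
  expect_lt(mean(cover), 1.0)
  expect_error(bootstrap_ci(numeric(0)), "empty")
})

test_that("relative improvement is computed on the printed-accuracy scale", {
  expect_equal(relative_improvement(50, 75), 50)
  expect_equal(relative_improvement(0.5, 0.75), 50)
  expect_error(relative_improvement(0, 10), "before")
})
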