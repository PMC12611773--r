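test_that("sample_random_triplets draws distinct items uniformly", {
  t3 <- sample_random_triplets(3, 20, seed = 1)
  expect_true(all(apply(t3, 1, sort) == c(1, 2, 3)))
  tt <- sample_random_triplets(40, 2000, seed = 2)
  expect_true(all(tt[, 1] != tt[, 2] & tt[, 1] != tt[, 3] & tt[, 2] != tt[, 3]))
  expect_error(sample_random_triplets(2, 5), "n_items")
  ## per-item inclusion approximately uniform (chi-square not rejected)
  big <- sample_random_triplets(100, 10000, seed = 3)
  counts <- tabulate(c(big), 100)
  p <- chisq.test(counts)$p.value
  expect_gt(p, 0.01)
  ## determinism
  expect_identical(big, sample_random_triplets(100, 10000, seed = 3))
})

test_that("class-boundary triplets have exactly two items sharing a label", {
  labels <- c("A", "A", "B")
  t1 <- sample_class_boundary_triplets(labels, 50, seed = 1)
  expect_true(all(t1[, 1] %in% 1:2 & t1[, 2] %in% 1:2 & t1[, 3] == 3))
  labels2 <- rep(letters[1:5], each = 6)
  t2 <- sample_class_boundary_triplets(labels2, 800, seed = 2)
  two_one <- labels2[t2[, 1]] == labels2[t2[, 2]] &
    labels2[t2[, 1]] != labels2[t2[, 3]]
  expect_true(all(two_one))
  ## pair class approximately uniform over the 5 classes
  freq <- table(labels2[t2[, 1]]) / nrow(t2)
  expect_true(all(abs(freq - 0.2) < 0.06))
  expect_error(sample_class_boundary_triplets(letters[1:4], 5), ">= 2")
})

test_that("cluster_representations and cluster-boundary sampling work together", {
  blobs <- withr::with_seed(4, rbind(
    matrix(rnorm(60, mean = 0, sd = 0.3), 30, 2),
    matrix(rnorm(60, mean = 20, sd = 0.3), 30, 2)))
  cl <- cluster_representations(blobs, 2, seed = 1)
  truth <- rep(1:2, each = 30)
  tab <- table(cl$labels, truth)
  expect_equal(sum(tab > 0), 2L)           # perfect two-blob partition
  ## c = n items -> inertia 0
  expect_equal(cluster_representations(blobs[1:10, ], 10, seed = 1)$inertia, 0)
  ## inertia non-increasing in c (best of restarts)
  inert <- vapply(2:6, function(c0)
    cluster_representations(blobs, c0, seed = 1)$inertia, numeric(1))
  expect_true(all(diff(inert) <= 1e-8))
  expect_error(cluster_representations(blobs, 100, seed = 1), "exceeds")
  ## boundary sampling over clusters satisfies the 2+1 constraint
  tb <- sample_cluster_boundary_triplets(cl, 300, seed = 5)
  lab <- cl$labels
  expect_true(all(lab[tb[, 1]] == lab[tb[, 2]] & lab[tb[, 1]] != lab[tb[, 3]]))
  ## equivalence with class-boundary sampling when clusters = classes
  expect_identical(tb, sample_class_boundary_triplets(lab, 300, seed = 5))
})

test_that("select_k_elbow finds a planted knee and flags flat curves", {
  planted <- withr::with_seed(6, do.call(rbind, lapply(1:4, function(g)
    matrix(rnorm(25 * 4, mean = 12 * g, sd = 0.4), 25, 4))))
  k <- select_k_elbow(planted, 2:8, seed = 1)
  expect_equal(as.integer(k), 4L)
  expect_false(attr(k, "low_curvature"))
  ## permutation invariance of the data rows
  perm <- withr::with_seed(7, sample(nrow(planted)))
  expect_equal(as.integer(select_k_elbow(planted[perm, ], 2:8, seed = 1)), 4L)
  ## featureless single Gaussian: documented fallback to smallest candidate
  flat <- withr::with_seed(8, matrix(rnorm(150 * 8), 150, 8))
  kf <- select_k_elbow(flat, 2:8, seed = 1)
  expect_equal(as.integer(kf), 2L)
  expect_true(attr(kf, "low_curvature"))
  expect_error(select_k_elbow(flat, c(4, 2, 8), seed = 1), "ascending")
})

test_that("levels-stratified sampling satisfies its per-level constraints", {
  ## unbalanced design: superclass sizes 20, 4, 4 items
  super <- c(rep("S1", 20), rep("S2", 4), rep("S3", 4))
  sub <- c(rep(c("s1a", "s1b"), each = 10), rep("s2a", 4), rep("s3a", 4))
  co <- sample_levels_triplets(super, sub, "coarse", 600, seed = 1)
  expect_true(all(apply(co, 1, function(t) length(unique(super[t])) == 3)))
  fi <- sample_levels_triplets(super, sub, "fine", 300, seed = 2)
  expect_true(all(apply(fi, 1, function(t) length(unique(sub[t])) == 1)))
  bo <- sample_levels_triplets(super, sub, "boundary", 300, seed = 3)
  expect_true(all(sub[bo[, 1]] == sub[bo[, 2]]))
  expect_true(all(super[bo[, 1]] != super[bo[, 3]]))
  ## superclass draws uniform over superclasses, not items: S1 holds 20/28
  ## of the items but appears as the pair class in about 1/3 of draws
  freq_s1 <- mean(super[bo[, 1]] == "S1")
  expect_lt(abs(freq_s1 - 1 / 3), 0.08)
  expect_gt(abs(freq_s1 - 20 / 28), 0.2)   # clearly not item-proportional
  ## nesting violation rejected
  bad_sub <- sub; bad_sub[1] <- "s2a"
  expect_error(sample_levels_triplets(super, bad_sub, "fine", 5), "nest")
})

test_that("pseudolabel stores softmax labels with argmax hard choices", {
  X <- withr::with_seed(9, matrix(rnorm(60), 10, 6))
  X[2, ] <- X[1, ]                          # exact duplicate pair
  ds <- pseudolabel(X, c(1, 2, 5))
  expect_equal(ds$choice, 1L)
  expect_gt(ds$soft[1, 1], 1 / 3)
  trips <- sample_random_triplets(10, 200, seed = 10)
  ds2 <- pseudolabel(X, trips)
  expect_equal(ds2$choice, max.col(ds2$soft, "first"))
  expect_equal(rowSums(ds2$soft), rep(1, 200))
  ## temperature -> 0 gives one-hot at the hard label
  ds_cold <- pseudolabel(X, trips, temperature = 1e-9)
  expect_equal(ds_cold$soft[cbind(1:200, ds2$choice)], rep(1, 200),
               tolerance = 1e-9)
  ## deterministic function of its inputs
  expect_identical(ds2$soft, pseudolabel(X, trips)$soft)
})
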