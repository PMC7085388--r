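test_that("euclidean_distance matches hand values and rejects bad input", {
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(euclidean_distance(c(1.5, -2), c(1.5, -2)), 0)
  expect_equal(euclidean_distance(c(1, 1, 1), c(2, 2, 2)), sqrt(3))
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)),
               euclidean_distance(c(3, 4), c(0, 0)))
  expect_error(euclidean_distance(c(1, 2), c(1, 2, 3)), "2.*3")
  expect_error(euclidean_distance(c(1, NA), c(0, 0)), "index 2")
  expect_error(euclidean_distance(c(Inf, 0), c(0, 0)), "index 1")
})

test_that("rkm_params validates its invariants and carries defaults", {
  p <- rkm_params()
  expect_equal(p$k, 2L)
  expect_equal(p$threshold, 1.4)
  expect_equal(p$w_lower, 0.7)
  expect_equal(p$w_upper, 0.3)
  expect_error(rkm_params(threshold = 0.9), ">= 1")
  expect_error(rkm_params(w_lower = 0.6, w_upper = 0.3), "equal 1")
  expect_error(rkm_params(k = 0), "positive integer")
  expect_error(rkm_params(w_lower = 0, w_upper = 1), "w_lower")
})

test_that("assign_object applies the distance-ratio test", {
  cents <- rbind(c(0, 0), c(10, 0))
  # ratio 9 > 1.4: certain member of cluster 1
  m <- assign_object(c(1, 0), cents, 1.4)
  expect_equal(m$nearest, 1L)
  expect_length(m$tied_set, 0)
  expect_false(m$is_ambiguous)
  # equidistant midpoint is ambiguous for any threshold >= 1
  m <- assign_object(c(5, 0), cents, 1.4)
  expect_equal(m$nearest, 1L) # lowest index on ties
  expect_equal(m$tied_set, 2L)
  expect_true(m$is_ambiguous)
  # ratio 1.5 straddles thresholds 1.4 and 1.6
  m14 <- assign_object(c(4, 0), cents, 1.4)
  expect_false(m14$is_ambiguous)
  m16 <- assign_object(c(4, 0), cents, 1.6)
  expect_equal(m16$tied_set, 2L)
  # coinciding with a centroid is unambiguous (no division by zero)
  m0 <- assign_object(c(0, 0), cents, 1e6)
  expect_false(m0$is_ambiguous)
  expect_error(assign_object(c(1, 0), cents, 0.5), "threshold")
  expect_error(assign_object(c(1, 0), matrix(numeric(0), 0, 2), 1.4),
               "centroid")
})

test_that("assign_all reproduces the worked four-point example", {
  X <- rbind(c(1, 0), c(4, 0), c(5, 0), c(9, 0))
  part <- assign_all(X, rbind(c(0, 0), c(10, 0)), 1.4)
  expect_equal(part$lower[[1]], c(1L, 2L))
  expect_equal(part$lower[[2]], 4L)
  expect_equal(part$boundary[[1]], 3L)
  expect_equal(part$boundary[[2]], 3L)
  expect_equal(part$n_objects, 4L)
  expect_length(check_rough_properties(part), 0)
})

test_that("assign_all limits: single cluster, crisp threshold, saturation", {
  X <- random_points(40, seed = 11)
  # k = 1: everything in the only lower approximation
  p1 <- assign_all(X, X[1, , drop = FALSE], 1.4)
  expect_equal(p1$lower[[1]], seq_len(40))
  expect_length(p1$boundary[[1]], 0)
  # threshold 1 without exact ties: crisp nearest-centroid assignment
  cents <- rbind(c(2, 2), c(8, 8))
  pc <- assign_all(X, cents, 1)
  expect_equal(sum(lengths(pc$lower)), 40)
  nearest <- apply(X, 1, function(x) {
    which.min(c(sqrt(sum((x - cents[1, ])^2)), sqrt(sum((x - cents[2, ])^2))))
  })
  expect_equal(sort(pc$lower[[1]]), which(nearest == 1))
  # huge threshold: every object ambiguous, in both boundaries
  ps <- assign_all(X, cents, 1e6)
  expect_equal(sum(lengths(ps$lower)), 0)
  expect_equal(ps$boundary[[1]], seq_len(40))
  expect_equal(ps$boundary[[2]], seq_len(40))
})

test_that("assign_all agrees with a brute-force ratio-test loop", {
  set.seed(99)
  for (case in 1:25) {
    n <- sample(5:100, 1)
    k <- sample(2:5, 1)
    p <- sample(1:4, 1)
    X <- matrix(runif(n * p, 0, 5), ncol = p)
    cents <- matrix(runif(k * p, 0, 5), ncol = p)
    thr <- runif(1, 1, 2)
    got <- assign_all(X, cents, thr)
    want <- brute_force_partition(X, cents, thr)
    expect_equal(lapply(got$lower, as.integer), lapply(want$lower, as.integer))
    expect_equal(lapply(got$boundary, as.integer),
                 lapply(want$boundary, as.integer))
  }
})

test_that("update_centroids blends lower and boundary means with fallbacks", {
  X <- rbind(c(0, 0), c(2, 0), c(4, 0), c(6, 0))
  base <- rbind(c(0, 0), c(9, 9))
  # plain mean when the boundary is empty
  p <- roughkm:::new_rough_partition(base, list(c(1L, 2L), integer(0)),
                                     list(integer(0), integer(0)), 4)
  expect_warning(up <- update_centroids(X, p), "no members")
  expect_equal(up[1, ], c(1, 0))
  expect_equal(up[2, ], c(9, 9)) # empty cluster frozen
  # weighted blend
  p <- roughkm:::new_rough_partition(base, list(c(1L, 2L), integer(0)),
                                     list(3L, 3L), 4)
  up <- update_centroids(X, p, w_lower = 0.7, w_upper = 0.3)
  expect_equal(up[1, ], c(0.7 * 1 + 0.3 * 4, 0))
  # boundary-only fallback
  expect_equal(up[2, ], c(4, 0))
  p <- roughkm:::new_rough_partition(base, list(integer(0), integer(0)),
                                     list(c(3L, 4L), c(3L, 4L)), 4)
  up <- update_centroids(X, p)
  expect_equal(up[1, ], c(5, 0))
})

test_that("fit on well-separated clouds finds clean clusters near the means", {
  sim <- simulate_overlap_data(n_per_class = 50, separation = 100,
                               overlap_fraction = 0, seed = 2)
  fit <- rough_kmeans(sim$dataset$X, rkm_params(k = 2, seed = 8))
  expect_true(fit$converged)
  expect_length(ambiguous_indices(fit), 0)
  # match fitted centroids to true means by nearest pairing
  true_means <- sim$truth$true_means
  for (j in 1:2) {
    d <- apply(fit$centroids, 1,
               function(c) sqrt(sum((c - true_means[j, ])^2)))
    expect_lt(min(d), 0.5)
  }
})

test_that("fit handles degenerate and invalid inputs", {
  one_point <- matrix(rep(c(3, 7), 5), ncol = 2, byrow = TRUE)
  fit <- rough_kmeans(one_point, rkm_params(k = 1, seed = 1))
  expect_equal(fit$centroids[1, ], c(3, 7))
  expect_true(fit$converged)
  expect_error(rough_kmeans(matrix(1, 1, 2), rkm_params(k = 2)),
               "at least k")
  df <- data.frame(a = c("x", "y", "z"))
  expect_error(rough_kmeans(df, rkm_params(k = 1)), "numeric")
  X <- matrix(c(1, NA, 3, 4), 2)
  expect_error(rough_kmeans(X, rkm_params(k = 1)), "preprocess")
})

test_that("fit is deterministic given the seed", {
  X <- random_points(80, seed = 4)
  a <- rough_kmeans(X, rkm_params(k = 3, w_lower = 0.7, w_upper = 0.3,
                                  seed = 21))
  b <- rough_kmeans(X, rkm_params(k = 3, w_lower = 0.7, w_upper = 0.3,
                                  seed = 21))
  expect_identical(a$centroids, b$centroids)
  expect_identical(a$lower, b$lower)
  expect_identical(a$boundary, b$boundary)
})

test_that("ambiguous set grows monotonically with the threshold", {
  X <- random_points(120, seed = 12)
  cents <- rbind(c(3, 3), c(7, 7), c(2, 8))
  prev <- integer(0)
  for (thr in c(1, 1.2, 1.4, 1.8, 2.5, 5)) {
    amb <- ambiguous_indices(assign_all(X, cents, thr))
    expect_true(all(prev %in% amb))
    prev <- amb
  }
})

test_that("check_rough_properties flags constructed violations", {
  cents <- rbind(c(0, 0), c(1, 1))
  ok <- roughkm:::new_rough_partition(cents, list(1:2, 3L),
                                      list(4L, 4L), 4)
  expect_length(check_rough_properties(ok), 0)
  # object 3 in two lower approximations
  bad1 <- roughkm:::new_rough_partition(cents, list(c(1L, 3L), c(2L, 3L)),
                                        list(integer(0), integer(0)), 3)
  expect_match(check_rough_properties(bad1), "P1.*index 3", all = FALSE)
  # object 5 in a single boundary set only
  bad3 <- roughkm:::new_rough_partition(cents, list(1:3, 4L),
                                        list(5L, integer(0)), 5)
  expect_match(check_rough_properties(bad3), "P3.*index 5", all = FALSE)
  # object in both a lower and a boundary set
  bad2 <- roughkm:::new_rough_partition(cents, list(1:2, 3:4),
                                        list(c(2L, 5L), 5L), 5)
  expect_match(check_rough_properties(bad2), "P2.*index 2", all = FALSE)
})

test_that("farthest-point initialization spans the data", {
  sim <- simulate_overlap_data(n_per_class = 30, separation = 30,
                               overlap_fraction = 0, seed = 6)
  fit <- rough_kmeans(sim$dataset$X,
                      rkm_params(k = 2, seed = 3, init = "farthest"))
  expect_true(fit$converged)
  expect_length(check_rough_properties(fit), 0)
  # one fitted centroid per true cluster
  d12 <- sqrt(sum((fit$centroids[1, ] - fit$centroids[2, ])^2))
  expect_gt(d12, 20)
})
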