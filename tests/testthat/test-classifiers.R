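test_that("rbf_kernel matches hand values and its defining properties", {
  expect_equal(rbf_kernel(c(1, 2), c(1, 2), sigma = 3), 1)
  expect_equal(rbf_kernel(c(0, 0), c(3, 4), sigma = 5), exp(-1))
  expect_equal(rbf_kernel(0, 2, sigma = 2), exp(-1)) # ||d||^2 == sigma^2
  expect_equal(rbf_kernel(c(0, 0), c(3, 4), sigma = 5, two_sigma_sq = TRUE),
               exp(-0.5))
  expect_error(rbf_kernel(1, 2, sigma = 0), "sigma")
  set.seed(10)
  for (i in 1:20) {
    x <- rnorm(3); y <- rnorm(3); s <- runif(1, 0.1, 4)
    v <- rbf_kernel(x, y, s)
    expect_gt(v, 0); expect_lte(v, 1)
    expect_equal(v, rbf_kernel(y, x, s))
    if (any(x != y)) expect_lt(v, 1)
  }
})

test_that("nb_posterior follows Bayes arithmetic and normalizes", {
  expect_equal(nb_posterior(c(0.5, 0.5), c(1, 1)), c(0.5, 0.5))
  expect_equal(nb_posterior(c(0.9, 0.1), c(2, 2)), c(0.9, 0.1))
  expect_equal(nb_posterior(c(0.5, 0.5), c(3, 1)), c(0.75, 0.25))
  # matrix likelihoods multiply across features
  lik <- rbind(c(0.5, 0.6), c(0.25, 0.3))
  post <- nb_posterior(c(0.5, 0.5), lik)
  expect_equal(post, c(0.8, 0.2))
  expect_equal(sum(post), 1)
  expect_error(nb_posterior(c(0.7, 0.7), c(1, 1)), "sum to 1")
  expect_error(nb_posterior(c(0.5, 0.5), c(0, 0)), "zero evidence")
})

test_that("knn_predict votes by Euclidean proximity with documented ties", {
  train <- roughkm:::new_disease_dataset(
    X = rbind(c(0, 0), c(0, 1), c(1, 0), c(10, 0), c(10, 1), c(11, 0)),
    y = c(0L, 0L, 0L, 1L, 1L, 1L), feature_names = c("a", "b"),
    positive_label = "1", provenance = "fixture")
  expect_equal(knn_predict(train, c(0, 0), n_neighbors = 1), 0L)
  expect_equal(knn_predict(train, c(10, 0), n_neighbors = 1), 1L)
  expect_equal(knn_predict(train, c(0.2, 0.2), n_neighbors = 3), 0L)
  # perfect 3-3 vote tie at the midpoint goes to the positive label
  expect_equal(knn_predict(train, c(5.25, 0.5), n_neighbors = 6), 1L)
  expect_error(knn_predict(train, c(0, 0), n_neighbors = 7), "exceeds")
})

test_that("entropy and information gain match hand-derived bits", {
  expect_equal(label_entropy(c(1, 1, 1, 1)), 0)
  expect_equal(label_entropy(c(0, 0, 1, 1)), 1)
  expect_equal(label_entropy(c(0, 0, 0, 1)),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)))
  # balanced binary is the entropy maximum
  set.seed(2)
  for (i in 1:10) {
    n1 <- sample(0:20, 1)
    expect_lte(label_entropy(c(rep(0, 20 - n1), rep(1, n1 + 1))), 1)
  }
  # perfectly predictive attribute: gain equals the label entropy
  s <- information_gain(c(0, 0, 1, 1), c("a", "a", "b", "b"))
  expect_equal(s$gain, 1)
  expect_equal(s$info_B_D, 0)
  # constant attribute: zero gain
  s <- information_gain(c(0, 0, 1, 1), rep("a", 4))
  expect_equal(s$gain, 0)
  # worked 4-row case
  s <- information_gain(c(0, 0, 1, 1), c("a", "a", "a", "b"))
  expect_equal(s$info_D, 1)
  expect_equal(s$info_B_D, 0.75 * label_entropy(c(0, 0, 1)))
  expect_equal(s$gain, 1 - 0.6887219, tolerance = 1e-6)
  expect_gte(s$gain, 0)
  expect_lte(s$gain, s$info_D)
})

test_that("all four classifiers separate clean blobs perfectly", {
  ds <- preprocess_dataset(make_blobs(n_per_class = 40, separation = 20,
                                      seed = 14)) # min-max scaled
  split <- split_train_test(ds, 0.7, seed = 3)
  for (method in c("naive_bayes", "svm_rbf", "knn", "random_forest")) {
    model <- train_classifier(split$train, classifier_spec(method, seed = 5))
    pred <- predict(model, split$test)
    expect_equal(pred, split$test$y, info = method)
    # training rows are also reproduced
    expect_equal(predict(model, split$train), split$train$y, info = method)
  }
})

test_that("fitted naive Bayes agrees with the explicit posterior oracle", {
  ds <- make_blobs(n_per_class = 60, separation = 3, seed = 21)
  model <- train_classifier(ds, classifier_spec("naive_bayes"))
  tabs <- model$fit$tables
  priors <- model$fit$apriori / sum(model$fit$apriori)
  set.seed(33)
  probe <- as.matrix(ds$X)[sample.int(120, 20), , drop = FALSE]
  for (i in seq_len(nrow(probe))) {
    lik <- sapply(seq_along(tabs), function(f) {
      stats::dnorm(probe[i, f], mean = tabs[[f]][, 1], sd = tabs[[f]][, 2])
    })
    post <- nb_posterior(as.numeric(priors), as.matrix(lik))
    want <- if (post[2] > post[1]) 1L else 0L
    got <- predict(model, probe[i, , drop = FALSE])
    expect_equal(got, want)
  }
})

test_that("classifier guards: single class, dimension mismatch, empty input", {
  ds <- make_blobs(n_per_class = 10, seed = 4)
  one_class <- subset_dataset(ds, which(ds$y == 0))
  expect_error(train_classifier(one_class, classifier_spec("knn")),
               "single class")
  model <- train_classifier(ds, classifier_spec("knn"))
  expect_error(predict(model, matrix(1, 2, 5)), "mismatch")
  expect_equal(predict(model, matrix(numeric(0), 0, 2)), integer(0))
})

test_that("random forest predictions are seed-deterministic", {
  sim <- simulate_overlap_data(n_per_class = 40, separation = 4,
                               overlap_fraction = 0.1, seed = 13)
  split <- split_train_test(sim$dataset, 0.7, seed = 1)
  p1 <- predict(train_classifier(split$train,
                                 classifier_spec("random_forest", seed = 77)),
                split$test)
  p2 <- predict(train_classifier(split$train,
                                 classifier_spec("random_forest", seed = 77)),
                split$test)
  expect_identical(p1, p2)
})
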