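#' Radial basis function kernel
#'
#' `exp(-||x - xbar||^2 / sigma^2)`, the similarity the RBF support vector
#' machine uses. The default convention divides the squared Euclidean
#' distance by `sigma^2`; set `two_sigma_sq = TRUE` for the `2 * sigma^2`
#' denominator used elsewhere in the literature.
#'
#' @param x,xbar Numeric feature vectors of equal length.
#' @param sigma Positive kernel width.
#' @param two_sigma_sq Use the `2 * sigma^2` denominator convention.
#' @return A value in (0, 1]; equals 1 iff `x == xbar`.
#' @examples
#' rbf_kernel(c(0, 0), c(3, 4), sigma = 5) # exp(-1)
#' @export
rbf_kernel <- function(x, xbar, sigma, two_sigma_sq = FALSE) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) {
    stop("`sigma` must be a positive real; got ", deparse(sigma))
  }
  d2 <- euclidean_distance(x, xbar)^2
  denom <- if (two_sigma_sq) 2 * sigma^2 else sigma^2
  exp(-d2 / denom)
}

#' Naive Bayes posterior from priors and likelihoods
#'
#' Combines class priors with per-class likelihood values for one object
#' under the conditional-independence assumption: the posterior is
#' proportional to `prior * prod(per-feature likelihoods)`, normalized to
#' sum to 1.
#'
#' @param priors Numeric vector of class prior probabilities (sums to 1).
#' @param likelihoods A matrix of per-class, per-feature likelihood values
#'   (classes in rows, features in columns), or a vector of one likelihood
#'   per class.
#' @return Posterior probability vector over classes (sums to 1).
#' @examples
#' nb_posterior(c(0.5, 0.5), c(3, 1)) # c(0.75, 0.25)
#' @export
nb_posterior <- function(priors, likelihoods) {
  if (abs(sum(priors) - 1) > 1e-8) {
    stop("`priors` must sum to 1; got ", sum(priors))
  }
  if (is.matrix(likelihoods)) {
    if (nrow(likelihoods) != length(priors)) {
      stop("likelihoods must have one row per class")
    }
    lik <- apply(likelihoods, 1, prod)
  } else {
    if (length(likelihoods) != length(priors)) {
      stop("need one likelihood per class")
    }
    lik <- likelihoods
  }
  joint <- priors * lik
  evidence <- sum(joint)
  if (evidence <= 0 || !is.finite(evidence)) {
    stop("zero evidence for every class: degenerate likelihoods")
  }
  joint / evidence
}

#' K-nearest-neighbour prediction for one object
#'
#' Majority vote among the `n_neighbors` training rows closest in Euclidean
#' distance. Distance ties are broken by training-row order; an even vote
#' split goes to the positive label (1).
#'
#' @param train A `"disease_dataset"` with a numeric feature matrix.
#' @param x Numeric feature vector to classify.
#' @param n_neighbors Number of neighbours (must not exceed the training
#'   size).
#' @return Predicted label, 0 or 1.
#' @export
knn_predict <- function(train, x, n_neighbors = 5) {
  X <- as_feature_matrix(train$X)
  n <- nrow(X)
  if (n == 0) stop("empty training set")
  if (n_neighbors > n) {
    stop("n_neighbors = ", n_neighbors, " exceeds training size ", n)
  }
  d <- sqrt(rowSums((X - matrix(x, n, length(x), byrow = TRUE))^2))
  ord <- order(d, seq_len(n)) # distance ties fall back to row order
  votes <- train$y[ord[seq_len(n_neighbors)]]
  pos <- sum(votes == 1)
  neg <- n_neighbors - pos
  if (pos >= neg) 1L else 0L # exact tie goes to the positive label
}

#' Shannon entropy of a label multiset, in bits
#'
#' @param labels Vector of class labels (any type).
#' @return `-sum(p_i * log2(p_i))` over observed classes, with
#'   `0 * log(0) = 0`.
#' @examples
#' label_entropy(c(0, 0, 1, 1)) # 1 bit
#' @export
label_entropy <- function(labels) {
  if (length(labels) == 0) stop("empty label set")
  p <- as.numeric(table(labels)) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Information gain of a discretized attribute
#'
#' Entropy reduction of the class label achieved by partitioning the
#' records on the attribute's levels: the decision-tree split criterion.
#'
#' @param labels Class labels.
#' @param attribute Discretized attribute values, same length.
#' @return A list of class `"split_score"` with `info_D` (label entropy in
#'   bits), `info_B_D` (attribute-conditional entropy) and `gain`.
#' @examples
#' information_gain(c(0, 0, 1, 1), c("a", "a", "a", "b"))$gain
#' @export
information_gain <- function(labels, attribute) {
  if (length(labels) != length(attribute)) {
    stop("labels and attribute must have equal length")
  }
  info_D <- label_entropy(labels)
  n <- length(labels)
  info_B_D <- 0
  for (lev in unique(attribute)) {
    sel <- attribute == lev
    info_B_D <- info_B_D + sum(sel) / n * label_entropy(labels[sel])
  }
  structure(
    list(info_D = info_D, info_B_D = info_B_D,
         gain = max(info_D - info_B_D, 0)),
    class = "split_score"
  )
}

#' Classifier specification
#'
#' @param method One of `"naive_bayes"`, `"svm_rbf"`, `"knn"`,
#'   `"random_forest"`.
#' @param sigma RBF kernel width for the SVM; `NULL` defaults to
#'   `1 / n_features` at training time (features are assumed min-max
#'   scaled).
#' @param two_sigma_sq RBF denominator convention flag (see
#'   [rbf_kernel()]).
#' @param cost SVM regularization constant C.
#' @param n_neighbors KNN neighbour count; odd by default to avoid binary
#'   vote ties.
#' @param n_trees,max_depth Random-forest size and depth cap (`NULL` =
#'   unlimited depth).
#' @param seed Seed for stochastic fits (random forest).
#' @return A list of class `"classifier_spec"`.
#' @export
classifier_spec <- function(method = c("naive_bayes", "svm_rbf", "knn",
                                       "random_forest"),
                            sigma = NULL, two_sigma_sq = FALSE, cost = 1,
                            n_neighbors = 5, n_trees = 100, max_depth = NULL,
                            seed = 42) {
  method <- match.arg(method)
  if (!is.null(sigma) && sigma <= 0) stop("`sigma` must be positive")
  if (n_neighbors < 1) stop("`n_neighbors` must be >= 1")
  if (n_trees < 1) stop("`n_trees` must be >= 1")
  structure(
    list(method = method, sigma = sigma, two_sigma_sq = two_sigma_sq,
         cost = cost, n_neighbors = as.integer(n_neighbors),
         n_trees = as.integer(n_trees), max_depth = max_depth,
         seed = as.integer(seed)),
    class = "classifier_spec"
  )
}

#' Train one of the four reference classifiers
#'
#' Fits the method named in `spec` on a numeric training dataset: Gaussian
#' naive Bayes (per-class, per-feature normal densities), an RBF-kernel
#' support vector machine (`gamma = 1 / sigma^2` so the kernel matches
#' [rbf_kernel()]'s convention), K-nearest neighbours (lazy: stores the
#' training data), or a seeded bagged random forest.
#'
#' @param train A `"disease_dataset"` with numeric features and both
#'   classes present.
#' @param spec A [classifier_spec()].
#' @return A `"trained_classifier"` for use with [predict()].
#' @export
train_classifier <- function(train, spec = classifier_spec()) {
  X <- as_feature_matrix(train$X)
  y <- factor(train$y, levels = c(0, 1))
  if (length(unique(train$y)) < 2) {
    stop("training set contains a single class; both classes are required")
  }
  fit <- switch(spec$method,
    naive_bayes = e1071::naiveBayes(x = as.data.frame(X), y = y),
    svm_rbf = {
      sigma <- if (is.null(spec$sigma)) 1 / ncol(X) else spec$sigma
      denom <- if (spec$two_sigma_sq) 2 * sigma^2 else sigma^2
      e1071::svm(x = X, y = y, kernel = "radial", gamma = 1 / denom,
                 cost = spec$cost, scale = FALSE)
    },
    knn = list(X = X, y = train$y), # lazy learner
    random_forest = with_seed(spec$seed, {
      randomForest::randomForest(
        x = as.data.frame(X), y = y, ntree = spec$n_trees,
        maxnodes = if (is.null(spec$max_depth)) NULL
                   else 2^spec$max_depth)
    })
  )
  structure(
    list(method = spec$method, spec = spec, fit = fit,
         feature_names = colnames(X), n_features = ncol(X),
         positive_label = train$positive_label),
    class = "trained_classifier"
  )
}

#' @export
print.trained_classifier <- function(x, ...) {
  cat(sprintf("Trained classifier: %s (%d features)\n",
              x$method, x$n_features))
  invisible(x)
}

#' Predict labels for new objects
#'
#' @param object A `"trained_classifier"`.
#' @param newdata Numeric feature matrix (or a `"disease_dataset"`).
#' @param ... Unused.
#' @return Integer vector of 0/1 labels, one per row (empty input gives an
#'   empty vector).
#' @export
predict.trained_classifier <- function(object, newdata, ...) {
  if (inherits(newdata, "disease_dataset")) newdata <- newdata$X
  X <- as_feature_matrix(newdata)
  if (nrow(X) == 0) return(integer(0))
  if (ncol(X) != object$n_features) {
    stop("dimension mismatch: model trained on ", object$n_features,
         " features, newdata has ", ncol(X))
  }
  colnames(X) <- object$feature_names
  out <- switch(object$method,
    naive_bayes = as.integer(as.character(
      stats::predict(object$fit, as.data.frame(X)))),
    svm_rbf = as.integer(as.character(stats::predict(object$fit, X))),
    knn = {
      train <- list(X = object$fit$X, y = object$fit$y)
      vapply(seq_len(nrow(X)), function(i) {
        knn_predict(train, X[i, ], object$spec$n_neighbors)
      }, integer(1))
    },
    random_forest = as.integer(as.character(
      stats::predict(object$fit, as.data.frame(X)))))
  as.integer(out)
}
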