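#' Rough K-means hyperparameters
#'
#' Bundles every tunable of the rough K-means algorithm. The ratio threshold
#' decides how much farther a rival centroid may be (relative to the nearest
#' one) while still claiming the object into its upper approximation; objects
#' claimed by two or more clusters fall into the boundary region and are the
#' "ambiguous" objects downstream stages may exclude.
#'
#' @param k Number of clusters (positive integer). Default 2, matching the
#'   binary disease/no-disease setting.
#' @param threshold Distance-ratio threshold, a real number >= 1. A rival
#'   cluster `j` ties with the nearest cluster `i` when
#'   `d(x, c_j) / d(x, c_i) <= threshold`. Default 1.4.
#' @param w_lower Weight of the lower-approximation mean in the centroid
#'   update, in (0, 1]. Default 0.7.
#' @param w_upper Weight of the boundary mean, in [0, 1). Default 0.3.
#'   `w_lower + w_upper` must equal 1.
#' @param max_iter Maximum number of assign/update sweeps. Default 300.
#' @param tol Convergence tolerance on the maximum centroid L2 shift.
#'   Default 1e-6.
#' @param seed Integer RNG seed for the initialization. Default 42.
#' @param init Initialization scheme. `"farthest"` (default) seeds the first
#'   centroid at a random data row and then greedily picks the row farthest
#'   from all chosen centroids, guaranteeing that well-separated clusters
#'   each receive a seed; `"rows"` samples `k` distinct data rows. Pure row
#'   sampling can start both centroids inside one cluster, a configuration
#'   from which the rough update cannot escape (the rival cluster's objects
#'   are all boundary objects pulling every centroid toward the global
#'   mean), so it is not the default.
#'
#' @return An object of class `"rkm_params"`.
#' @examples
#' rkm_params()
#' rkm_params(k = 3, threshold = 1.2, w_lower = 0.8, w_upper = 0.2)
#' @export
rkm_params <- function(k = 2, threshold = 1.4, w_lower = 0.7, w_upper = 0.3,
                       max_iter = 300, tol = 1e-6, seed = 42,
                       init = c("farthest", "rows")) {
  init <- match.arg(init)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k)) {
    stop("`k` must be a positive integer, got ", deparse(k))
  }
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 1) {
    stop("`threshold` must be a real number >= 1 (a farther-to-nearest ",
         "distance ratio below 1 is impossible); got ", deparse(threshold))
  }
  if (!is.numeric(w_lower) || w_lower <= 0 || w_lower > 1) {
    stop("`w_lower` must lie in (0, 1]; got ", deparse(w_lower))
  }
  if (!is.numeric(w_upper) || w_upper < 0 || w_upper >= 1) {
    stop("`w_upper` must lie in [0, 1); got ", deparse(w_upper))
  }
  if (abs(w_lower + w_upper - 1) > 1e-12) {
    stop("`w_lower` + `w_upper` must equal 1; got ",
         w_lower, " + ", w_upper, " = ", w_lower + w_upper)
  }
  if (!is.numeric(max_iter) || max_iter < 1) stop("`max_iter` must be >= 1")
  if (!is.numeric(tol) || tol < 0) stop("`tol` must be nonnegative")
  structure(
    list(k = as.integer(k), threshold = threshold,
         w_lower = w_lower, w_upper = w_upper,
         max_iter = as.integer(max_iter), tol = tol,
         seed = as.integer(seed), init = init),
    class = "rkm_params"
  )
}

#' @export
print.rkm_params <- function(x, ...) {
  cat("Rough K-means parameters\n")
  cat(sprintf("  k = %d, threshold = %g, w_lower = %g, w_upper = %g\n",
              x$k, x$threshold, x$w_lower, x$w_upper))
  cat(sprintf("  max_iter = %d, tol = %g, seed = %d, init = %s\n",
              x$max_iter, x$tol, x$seed, x$init))
  invisible(x)
}

#' Euclidean distance between two feature vectors
#'
#' @param a,b Numeric vectors of equal length with finite entries.
#' @return The nonnegative distance `sqrt(sum((a - b)^2))`.
#' @examples
#' euclidean_distance(c(0, 0), c(3, 4)) # 5
#' @export
euclidean_distance <- function(a, b) {
  if (length(a) != length(b)) {
    stop("dimension mismatch: length(a) = ", length(a),
         ", length(b) = ", length(b))
  }
  bad <- which(!is.finite(a) | !is.finite(b))
  if (length(bad) > 0) {
    stop("non-finite entry at index ", bad[1])
  }
  sqrt(sum((a - b)^2))
}

#' Rough membership of a single object
#'
#' Computes the distance-ratio test for one object against a set of
#' centroids. The nearest centroid `i` minimizes the Euclidean distance
#' (ties broken toward the lowest cluster index); the tie set `T` collects
#' every other cluster `j` with `d(x, c_j) / d(x, c_i) <= threshold`. An
#' empty tie set places the object in the lower approximation of cluster
#' `i`; a nonempty one makes the object ambiguous, belonging to the boundary
#' of cluster `i` and of every cluster in `T`. An object coinciding with its
#' nearest centroid (zero distance) is unambiguous by convention, which also
#' avoids a division by zero.
#'
#' @param x Numeric feature vector.
#' @param centroids A matrix with one centroid per row (or a list of
#'   vectors).
#' @param threshold Ratio threshold, >= 1.
#' @return A list of class `"rkm_membership"` with elements `nearest`
#'   (cluster index), `tied_set` (integer vector, possibly empty) and
#'   `is_ambiguous` (logical).
#' @examples
#' assign_object(c(1, 0), rbind(c(0, 0), c(10, 0)), threshold = 1.4)
#' @export
assign_object <- function(x, centroids, threshold) {
  centroids <- as_centroid_matrix(centroids)
  if (nrow(centroids) < 1) stop("at least one centroid is required")
  if (threshold < 1) stop("`threshold` must be >= 1; got ", threshold)
  d <- vapply(seq_len(nrow(centroids)),
              function(j) euclidean_distance(x, centroids[j, ]),
              numeric(1))
  nearest <- which.min(d) # lowest index on exact ties
  if (d[nearest] == 0) {
    tied <- integer(0)
  } else {
    ratio <- d / d[nearest]
    tied <- setdiff(which(ratio <= threshold), nearest)
  }
  structure(
    list(nearest = as.integer(nearest), tied_set = as.integer(tied),
         is_ambiguous = length(tied) > 0),
    class = "rkm_membership"
  )
}

as_centroid_matrix <- function(centroids) {
  if (is.list(centroids)) centroids <- do.call(rbind, centroids)
  if (is.null(dim(centroids))) centroids <- matrix(centroids, nrow = 1)
  storage.mode(centroids) <- "double"
  centroids
}

as_feature_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  if (!is.numeric(X)) {
    stop("feature matrix must be numeric; run preprocessing first")
  }
  storage.mode(X) <- "double"
  X
}

#' Rough assignment of every object
#'
#' Vectorized sweep of [assign_object()] over the rows of `X`, producing a
#' rough partition: per-cluster lower-approximation and boundary index sets.
#'
#' @param X Numeric feature matrix (objects in rows).
#' @param centroids Matrix with one centroid per row.
#' @param threshold Ratio threshold, >= 1.
#' @return A `"rough_partition"`: list with `centroids`, `lower` and
#'   `boundary` (each a list of `k` integer index vectors, 1-based row
#'   indices of `X`), and `n_objects`.
#' @examples
#' X <- rbind(c(1, 0), c(4, 0), c(5, 0), c(9, 0))
#' assign_all(X, rbind(c(0, 0), c(10, 0)), threshold = 1.4)
#' @export
assign_all <- function(X, centroids, threshold) {
  X <- as_feature_matrix(X)
  centroids <- as_centroid_matrix(centroids)
  n <- nrow(X)
  k <- nrow(centroids)
  if (n < 1) stop("`X` must contain at least one object")
  if (k < 1) stop("at least one centroid is required")
  if (threshold < 1) stop("`threshold` must be >= 1; got ", threshold)
  if (ncol(X) != ncol(centroids)) {
    stop("dimension mismatch: objects have ", ncol(X),
         " features, centroids have ", ncol(centroids))
  }
  bad <- which(!is.finite(X))
  if (length(bad) > 0) {
    stop("non-finite entry at row ", ((bad[1] - 1) %% n) + 1)
  }

  # squared distances via the expansion |x|^2 - 2 x.c + |c|^2
  D2 <- outer(rowSums(X^2), rep(1, k)) - 2 * X %*% t(centroids) +
    outer(rep(1, n), rowSums(centroids^2))
  D <- sqrt(pmax(D2, 0))
  nearest <- max.col(-D, ties.method = "first")
  dmin <- D[cbind(seq_len(n), nearest)]

  # tie matrix: rival cluster close enough relative to the nearest one
  tied <- D <= (dmin * threshold)
  tied[cbind(seq_len(n), nearest)] <- FALSE
  tied[dmin == 0, ] <- FALSE # coincides with a centroid: unambiguous
  ambiguous <- rowSums(tied) > 0

  lower <- vector("list", k)
  boundary <- vector("list", k)
  for (j in seq_len(k)) {
    lower[[j]] <- which(!ambiguous & nearest == j)
    boundary[[j]] <- which(ambiguous & (nearest == j | tied[, j]))
  }
  new_rough_partition(centroids, lower, boundary, n)
}

new_rough_partition <- function(centroids, lower, boundary, n_objects,
                                iterations = NA_integer_, converged = NA) {
  structure(
    list(centroids = centroids,
         lower = lapply(lower, as.integer),
         boundary = lapply(boundary, as.integer),
         n_objects = as.integer(n_objects),
         iterations = iterations, converged = converged),
    class = "rough_partition"
  )
}

#' @export
print.rough_partition <- function(x, ...) {
  k <- length(x$lower)
  n_low <- sum(lengths(x$lower))
  n_amb <- x$n_objects - n_low
  cat(sprintf("Rough partition: %d objects, %d clusters\n", x$n_objects, k))
  cat(sprintf("  lower approximations: %d objects (%s)\n",
              n_low, paste(lengths(x$lower), collapse = " + ")))
  cat(sprintf("  boundary region: %d ambiguous objects\n", n_amb))
  if (!is.na(x$iterations)) {
    cat(sprintf("  converged: %s after %d iterations\n",
                ifelse(isTRUE(x$converged), "yes", "no"), x$iterations))
  }
  invisible(x)
}

#' Indices of ambiguous (boundary-region) objects
#'
#' @param partition A `"rough_partition"`.
#' @return Sorted integer vector of row indices lying in any boundary set.
#' @export
ambiguous_indices <- function(partition) {
  sort(unique(unlist(partition$boundary)))
}

#' Weighted rough centroid update
#'
#' For each cluster the new centroid blends the mean of its lower
#' approximation (weight `w_lower`) with the mean of its boundary members
#' (weight `w_upper`). Degenerate cases fall back gracefully: an empty
#' boundary gives the plain lower mean, an empty lower approximation gives
#' the boundary mean, and a cluster with neither keeps its old centroid
#' (with a warning).
#'
#' @param X Numeric feature matrix the partition indexes into.
#' @param partition A `"rough_partition"`.
#' @param w_lower,w_upper Blend weights summing to 1.
#' @return Matrix of updated centroids, one per row.
#' @export
update_centroids <- function(X, partition, w_lower = 0.7, w_upper = 0.3) {
  X <- as_feature_matrix(X)
  k <- length(partition$lower)
  out <- as_centroid_matrix(partition$centroids)
  for (j in seq_len(k)) {
    lo <- partition$lower[[j]]
    bo <- partition$boundary[[j]]
    if (length(lo) > 0 && length(bo) > 0) {
      out[j, ] <- w_lower * colMeans(X[lo, , drop = FALSE]) +
        w_upper * colMeans(X[bo, , drop = FALSE])
    } else if (length(lo) > 0) {
      out[j, ] <- colMeans(X[lo, , drop = FALSE])
    } else if (length(bo) > 0) {
      out[j, ] <- colMeans(X[bo, , drop = FALSE])
    } else {
      warning("cluster ", j, " has no members; centroid left unchanged")
    }
  }
  out
}

init_centroids <- function(X, params) {
  n <- nrow(X)
  with_seed(params$seed, {
    if (params$init == "rows") {
      X[sample.int(n, params$k), , drop = FALSE]
    } else {
      idx <- sample.int(n, 1)
      dmin <- sqrt(rowSums((X - matrix(X[idx, ], n, ncol(X),
                                       byrow = TRUE))^2))
      while (length(idx) < params$k) {
        idx <- c(idx, which.max(dmin))
        d_new <- sqrt(rowSums((X - matrix(X[idx[length(idx)], ], n, ncol(X),
                                          byrow = TRUE))^2))
        dmin <- pmin(dmin, d_new)
      }
      X[idx, , drop = FALSE]
    }
  })
}

# Evaluate `expr` under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Fit rough K-means
#'
#' Alternates rough assignment ([assign_all()]) and weighted centroid
#' updates ([update_centroids()]) from a seeded initialization until the
#' maximum centroid shift drops below `tol` or `max_iter` is reached. The
#' result is deterministic given the data and parameters (including the
#' seed).
#'
#' @param X Numeric feature matrix or data frame (objects in rows); must be
#'   fully numeric and finite — run [preprocess_dataset()] first for raw
#'   tables.
#' @param params An [rkm_params()] object.
#' @param centroids Optional explicit initial centroid matrix (`k` rows);
#'   overrides the seeded initialization, e.g. to seed from class means.
#' @return A `"rough_partition"` with the final `centroids`, `lower` and
#'   `boundary` sets, plus `iterations` and `converged`.
#' @examples
#' set.seed(1)
#' X <- rbind(matrix(rnorm(60), ncol = 2),
#'            matrix(rnorm(60, mean = 10), ncol = 2))
#' fit <- rough_kmeans(X, rkm_params(k = 2, seed = 7))
#' fit
#' @export
rough_kmeans <- function(X, params = rkm_params(), centroids = NULL) {
  X <- as_feature_matrix(X)
  n <- nrow(X)
  if (n < params$k) {
    stop("need at least k = ", params$k, " objects; got ", n)
  }
  if (any(!is.finite(X))) {
    stop("`X` contains non-finite values; impute/encode with ",
         "preprocess_dataset() before clustering")
  }
  cent <- if (is.null(centroids)) init_centroids(X, params)
          else as_centroid_matrix(centroids)
  if (nrow(cent) != params$k) {
    stop("initial centroids must have k = ", params$k, " rows")
  }
  part <- NULL
  converged <- FALSE
  iter <- 0L
  while (iter < params$max_iter) {
    iter <- iter + 1L
    part <- assign_all(X, cent, params$threshold)
    new_cent <- update_centroids(X, part, params$w_lower, params$w_upper)
    shift <- max(sqrt(rowSums((new_cent - cent)^2)))
    cent <- new_cent
    if (shift < params$tol) {
      converged <- TRUE
      break
    }
  }
  part <- assign_all(X, cent, params$threshold)
  part$centroids <- cent
  part$iterations <- iter
  part$converged <- converged
  part$params <- params
  part
}

#' Validate the rough-set properties of a partition
#'
#' Checks the defining invariants of a rough partition: each object belongs
#' to at most one lower approximation (P1); upper approximations contain
#' their lower approximations, i.e. no object sits in both the lower and a
#' boundary set (P2, by the lower/boundary representation); an object in no
#' lower approximation belongs to at least two boundary sets (P3); and
#' every object is covered exactly once under this rule.
#'
#' @param partition A `"rough_partition"`.
#' @return Character vector of violations (empty when the partition is
#'   valid), each naming the property and the offending object index.
#' @export
check_rough_properties <- function(partition) {
  n <- partition$n_objects
  k <- length(partition$lower)
  lower_count <- integer(n)
  boundary_count <- integer(n)
  for (j in seq_len(k)) {
    lower_count[partition$lower[[j]]] <- lower_count[partition$lower[[j]]] + 1L
    boundary_count[partition$boundary[[j]]] <-
      boundary_count[partition$boundary[[j]]] + 1L
  }
  violations <- character(0)
  for (i in seq_len(n)) {
    if (lower_count[i] > 1) {
      violations <- c(violations, sprintf(
        "P1 violation at index %d: in %d lower approximations",
        i, lower_count[i]))
    }
    if (lower_count[i] >= 1 && boundary_count[i] > 0) {
      violations <- c(violations, sprintf(
        "P2 violation at index %d: in a lower approximation and %d boundary set(s)",
        i, boundary_count[i]))
    }
    if (lower_count[i] == 0 && boundary_count[i] < 2) {
      violations <- c(violations, sprintf(
        "P3 violation at index %d: in no lower approximation but only %d boundary set(s)",
        i, boundary_count[i]))
    }
  }
  violations
}
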