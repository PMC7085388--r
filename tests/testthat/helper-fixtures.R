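# Shared fixtures: all data is generated in code at test time.

# Two well-separated Gaussian blobs as a numeric disease_dataset.
make_blobs <- function(n_per_class = 30, n_features = 2, separation = 20,
                       spread = 1, seed = 1) {
  sim <- simulate_overlap_data(n_per_class = n_per_class,
                               n_features = n_features,
                               separation = separation, spread = spread,
                               overlap_fraction = 0, seed = seed)
  sim$dataset
}

# Random unstructured points for clustering property tests.
random_points <- function(n, p = 2, seed = 1) {
  set.seed(seed)
  matrix(runif(n * p, 0, 10), ncol = p)
}

# Brute-force reference for the rough assignment sweep: explicit per-object
# distance loop plus the ratio test, independent of assign_all's vectorized
# path.
brute_force_partition <- function(X, centroids, threshold) {
  X <- as.matrix(X)
  k <- nrow(centroids)
  lower <- rep(list(integer(0)), k)
  boundary <- rep(list(integer(0)), k)
  for (i in seq_len(nrow(X))) {
    d <- numeric(k)
    for (j in seq_len(k)) d[j] <- sqrt(sum((X[i, ] - centroids[j, ])^2))
    nearest <- which.min(d)
    tied <- integer(0)
    if (d[nearest] > 0) {
      for (j in seq_len(k)) {
        if (j != nearest && d[j] / d[nearest] <= threshold) tied <- c(tied, j)
      }
    }
    if (length(tied) == 0) {
      lower[[nearest]] <- c(lower[[nearest]], i)
    } else {
      for (j in c(nearest, tied)) boundary[[j]] <- c(boundary[[j]], i)
    }
  }
  list(lower = lower, boundary = boundary)
}

# Small mixed-type CSV in the kidney style, written to a temp file.
write_mixed_csv <- function(path, n = 12, seed = 7) {
  set.seed(seed)
  df <- data.frame(
    age = c(sample(20:80, n - 2, replace = TRUE), NA, 50),
    pressure = sample(60:120, n, replace = TRUE),
    appetite = c(sample(c("good", "poor"), n - 1, replace = TRUE), NA),
    class = rep(c("sick", "healthy"), length.out = n),
    stringsAsFactors = FALSE
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "?")
  df
}
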