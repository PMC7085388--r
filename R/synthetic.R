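#' Synthetic two-class generator with planted class overlap
#'
#' Draws two spherical Gaussian clouds and then re-positions a seeded
#' fraction of the rows into the region halfway between the class means —
#' the planted-ambiguous set. Those rows keep their class labels (the
#' ambiguity is positional, not label noise), emulating records whose
#' measurements show traits of both classes. Optional missing-value masking
#' and binary nominal columns emulate mixed clinical schemas such as the
#' kidney table.
#'
#' Defaults describe a clearly separated binary problem (mean distance
#' eight standard deviations) with 10% of records planted in the overlap
#' region, so that ambiguity comes from the plant, not the tails.
#'
#' @param n_per_class Records per class (default 200).
#' @param n_features Numeric feature count (default 2).
#' @param class_means Two mean vectors (2 x `n_features` matrix or list of
#'   two vectors); `NULL` places them `separation` apart along the
#'   all-ones direction.
#' @param separation Euclidean distance between the default class means, in
#'   units of `spread` (default 8).
#' @param spread Per-class standard deviation (default 1).
#' @param overlap_fraction Share of all rows re-positioned near the
#'   inter-mean midpoint, in \[0, 1) (default 0.1). Planted rows get
#'   Gaussian jitter of scale `spread / 2` around the midpoint.
#' @param missing_rate Probability of masking each feature entry as
#'   missing (default 0; masked output is a data frame).
#' @param nominal_columns Number of binary nominal columns appended
#'   (default 0; level frequencies differ by class so they carry signal).
#' @param seed RNG seed; the draw is fully determined by it.
#' @return A list with `dataset` (a `"disease_dataset"`) and `truth` (class
#'   `"synthetic_truth"`: `true_means`, `labels`, logical
#'   `planted_ambiguous`, `n_planted`).
#' @examples
#' sim <- simulate_overlap_data(n_per_class = 50, seed = 1)
#' sum(sim$truth$planted_ambiguous)
#' @export
simulate_overlap_data <- function(n_per_class = 200, n_features = 2,
                                  class_means = NULL, separation = 8,
                                  spread = 1, overlap_fraction = 0.1,
                                  missing_rate = 0, nominal_columns = 0,
                                  seed = 42) {
  if (n_per_class < 1 || n_features < 1) {
    stop("`n_per_class` and `n_features` must be positive")
  }
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop("`overlap_fraction` must lie in [0, 1)")
  }
  if (spread <= 0) stop("`spread` must be positive")
  if (is.null(class_means)) {
    unit <- rep(1 / sqrt(n_features), n_features)
    class_means <- rbind(rep(0, n_features), separation * spread * unit)
  } else if (is.list(class_means)) {
    class_means <- do.call(rbind, class_means)
  }
  stopifnot(nrow(class_means) == 2, ncol(class_means) == n_features)

  n_total <- 2L * n_per_class
  n_planted <- round(overlap_fraction * n_total)
  midpoint <- colMeans(class_means)

  with_seed(seed, {
    X <- rbind(
      matrix(stats::rnorm(n_per_class * n_features, sd = spread),
             ncol = n_features, byrow = TRUE) +
        matrix(class_means[1, ], n_per_class, n_features, byrow = TRUE),
      matrix(stats::rnorm(n_per_class * n_features, sd = spread),
             ncol = n_features, byrow = TRUE) +
        matrix(class_means[2, ], n_per_class, n_features, byrow = TRUE))
    y <- rep(c(0L, 1L), each = n_per_class)

    planted <- rep(FALSE, n_total)
    if (n_planted > 0) {
      idx <- sample.int(n_total, n_planted)
      planted[idx] <- TRUE
      X[idx, ] <- matrix(midpoint, n_planted, n_features, byrow = TRUE) +
        matrix(stats::rnorm(n_planted * n_features, sd = spread / 2),
               ncol = n_features, byrow = TRUE)
    }

    feature_names <- paste0("feature_", seq_len(n_features))
    colnames(X) <- feature_names
    Xout <- X
    types <- rep("numeric", n_features)

    if (nominal_columns > 0) {
      Xout <- as.data.frame(Xout)
      for (j in seq_len(nominal_columns)) {
        p <- ifelse(y == 1, 0.8, 0.2) # class-dependent level frequencies
        col <- ifelse(stats::runif(n_total) < p, "present", "absent")
        nm <- paste0("nominal_", j)
        Xout[[nm]] <- col
        feature_names <- c(feature_names, nm)
        types <- c(types, "nominal")
      }
    }
    if (missing_rate > 0) {
      if (!is.data.frame(Xout)) Xout <- as.data.frame(Xout)
      for (j in seq_along(Xout)) {
        mask <- stats::runif(n_total) < missing_rate
        Xout[[j]][mask] <- NA
      }
    }

    dataset <- new_disease_dataset(
      X = Xout, y = y, feature_names = feature_names,
      positive_label = "1",
      provenance = sprintf("synthetic overlap=%g seed=%d",
                           overlap_fraction, seed),
      feature_types = types
    )
    truth <- structure(
      list(true_means = class_means, labels = y,
           planted_ambiguous = planted, n_planted = as.integer(n_planted)),
      class = "synthetic_truth"
    )
    list(dataset = dataset, truth = truth)
  })
}

#' Recall of planted-ambiguous rows by a rough partition
#'
#' The share of rows planted in the class-overlap region that the rough
#' partition placed in a boundary set. With no planted rows the recall is
#' defined as 1 (nothing to find, nothing missed).
#'
#' @param partition A `"rough_partition"` fitted on the synthetic dataset.
#' @param truth The matching `"synthetic_truth"`.
#' @return A fraction in \[0, 1\].
#' @export
ambiguity_recall <- function(partition, truth) {
  if (partition$n_objects != length(truth$planted_ambiguous)) {
    stop("partition covers ", partition$n_objects, " objects but truth has ",
         length(truth$planted_ambiguous))
  }
  planted <- which(truth$planted_ambiguous)
  if (length(planted) == 0) return(1)
  flagged <- ambiguous_indices(partition)
  mean(planted %in% flagged)
}
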