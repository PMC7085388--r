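#' Split a dataset into retained and ambiguous rows
#'
#' Rows lying in any boundary set of the rough partition are the ambiguous
#' objects; the rest sit in exactly one lower approximation and are
#' retained. The two parts are disjoint and together cover every original
#' row; original row indices are preserved in each part's `row_indices`.
#'
#' @param dataset A `"disease_dataset"` the partition was fitted on.
#' @param partition A `"rough_partition"` over the same rows.
#' @return A list with `retained` and `ambiguous` (`"disease_dataset"`s)
#'   and `ambiguous_rows` (original indices).
#' @export
filter_ambiguous <- function(dataset, partition) {
  n <- n_records(dataset)
  if (partition$n_objects != n) {
    stop("partition covers ", partition$n_objects,
         " objects but dataset has ", n, " rows")
  }
  amb <- ambiguous_indices(partition)
  keep <- setdiff(seq_len(n), amb)
  list(
    retained = subset_dataset(dataset, keep, tag = "lower approximation"),
    ambiguous = subset_dataset(dataset, amb, tag = "boundary region"),
    ambiguous_rows = amb
  )
}

# Largest-remainder apportionment of the train quota across classes, so
# the total matches ceiling(fraction * n) while staying stratified.
stratified_quota <- function(n_by_class, fraction) {
  total <- ceiling(fraction * sum(n_by_class))
  base <- floor(fraction * n_by_class)
  rem <- fraction * n_by_class - base
  short <- total - sum(base)
  if (short > 0) {
    give <- order(rem, n_by_class, decreasing = TRUE)[seq_len(short)]
    base[give] <- base[give] + 1
  }
  pmin(base, n_by_class)
}

#' Stratified train/test split
#'
#' Seeded random split preserving the class mix: the train side gets
#' `ceiling(fraction * n)` rows, apportioned across the two classes by
#' largest remainder; the rest form the test side. Both classes must have
#' at least two members.
#'
#' @param dataset A `"disease_dataset"`.
#' @param fraction Train share in (0, 1) (default 0.7).
#' @param seed RNG seed.
#' @return A list with `train` and `test` datasets (disjoint, covering).
#' @export
split_train_test <- function(dataset, fraction = 0.7, seed = 42) {
  if (fraction <= 0 || fraction >= 1) {
    stop("`fraction` must lie strictly between 0 and 1")
  }
  y <- dataset$y
  classes <- sort(unique(y))
  sizes <- vapply(classes, function(c) sum(y == c), integer(1))
  if (any(sizes < 2)) {
    stop("stratification requires >= 2 members per class; class ",
         classes[which.min(sizes)], " has ", min(sizes))
  }
  quota <- stratified_quota(sizes, fraction)
  with_seed(seed, {
    train_idx <- integer(0)
    for (ci in seq_along(classes)) {
      rows <- which(y == classes[ci])
      train_idx <- c(train_idx, sample(rows, quota[ci]))
    }
    train_idx <- sort(train_idx)
    test_idx <- setdiff(seq_along(y), train_idx)
    list(train = subset_dataset(dataset, train_idx, tag = "train"),
         test = subset_dataset(dataset, test_idx, tag = "test"))
  })
}

#' Experiment configuration
#'
#' Everything [run_experiment()] needs: the preprocessing, clustering,
#' classifier and split settings of a paired baseline-versus-filtered run.
#'
#' @param preprocess A [preprocess_config()], or `NULL` to use the features
#'   as given (they must already be numeric and complete).
#' @param rkm An [rkm_params()]; the cluster count defaults to 2, one per
#'   class.
#' @param classifiers Named list of [classifier_spec()]s; defaults to all
#'   four reference methods.
#' @param split_fraction Train share (default 0.70).
#' @param split_seed Seed for the train/test draw (default 42).
#' @param filter_stage `"before_split"` fits the rough clustering on the
#'   whole table and drops ambiguous rows before splitting (whole-dataset
#'   lower/boundary counts are reported); `"train_only"` splits first and
#'   filters only the training rows, leaving the test set untouched.
#' @return A list of class `"experiment_config"`.
#' @export
experiment_config <- function(preprocess = preprocess_config(),
                              rkm = rkm_params(),
                              classifiers = default_classifiers(),
                              split_fraction = 0.7, split_seed = 42,
                              filter_stage = c("before_split", "train_only")) {
  filter_stage <- match.arg(filter_stage)
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop("`split_fraction` must lie strictly between 0 and 1")
  }
  if (is.null(names(classifiers)) || any(names(classifiers) == "")) {
    names(classifiers) <- vapply(classifiers, `[[`, character(1), "method")
  }
  structure(
    list(preprocess = preprocess, rkm = rkm, classifiers = classifiers,
         split_fraction = split_fraction, split_seed = split_seed,
         filter_stage = filter_stage),
    class = "experiment_config"
  )
}

#' The four reference classifier specs
#' @param seed Seed shared by the stochastic fits.
#' @return Named list of [classifier_spec()]s.
#' @export
default_classifiers <- function(seed = 42) {
  list(
    naive_bayes = classifier_spec("naive_bayes", seed = seed),
    svm_rbf = classifier_spec("svm_rbf", seed = seed),
    knn = classifier_spec("knn", seed = seed),
    random_forest = classifier_spec("random_forest", seed = seed)
  )
}

train_and_score <- function(train, test, specs) {
  lapply(specs, function(spec) {
    model <- train_classifier(train, spec)
    pred <- predict(model, test)
    counts <- confusion_counts(test$y, pred, positive_label = 1)
    list(counts = counts, metrics = compute_metrics(counts),
         n_train = n_records(train), n_test = n_records(test))
  })
}

#' Run the paired baseline / ambiguity-filtered experiment
#'
#' The baseline arm splits the (preprocessed) dataset, trains every
#' configured classifier and scores it on the held-out test rows. The
#' filtered arm first fits rough K-means on the features alone (labels
#' withheld), excludes the boundary-region rows, then splits, trains and
#' scores on what remains. Both arms share the split seed, so the only
#' difference is the exclusion of ambiguous objects.
#'
#' @param dataset A `"disease_dataset"` (raw or already numeric).
#' @param config An [experiment_config()].
#' @return An `"experiment_report"`: `partition_counts`
#'   (`n_lower`/`n_boundary` over the rows the clustering saw), `baseline`
#'   and `rkm` per-classifier results (confusion counts + metrics),
#'   `excluded_rows` (original indices), and a `config` echo.
#' @export
run_experiment <- function(dataset, config = experiment_config()) {
  data <- if (is.null(config$preprocess)) {
    dataset
  } else {
    tryCatch(preprocess_dataset(dataset, config$preprocess),
             error = function(e) stop("preprocess stage: ",
                                      conditionMessage(e), call. = FALSE))
  }
  if (!is.numeric(as_feature_matrix(data$X))) {
    stop("features must be numeric after preprocessing")
  }

  baseline_split <- split_train_test(data, config$split_fraction,
                                     config$split_seed)
  baseline <- tryCatch(
    train_and_score(baseline_split$train, baseline_split$test,
                    config$classifiers),
    error = function(e) stop("baseline classification stage: ",
                             conditionMessage(e), call. = FALSE))

  if (config$filter_stage == "before_split") {
    part <- rough_kmeans(data$X, config$rkm)
    filt <- filter_ambiguous(data, part)
    if (n_records(filt$retained) == 0) {
      stop("ambiguity filter stage: nothing retained ",
           "(every object is ambiguous at threshold ",
           config$rkm$threshold, ")", call. = FALSE)
    }
    rkm_split <- split_train_test(filt$retained, config$split_fraction,
                                  config$split_seed)
  } else {
    part <- rough_kmeans(baseline_split$train$X, config$rkm)
    filt <- filter_ambiguous(baseline_split$train, part)
    if (n_records(filt$retained) == 0) {
      stop("ambiguity filter stage: nothing retained ",
           "(every training object is ambiguous at threshold ",
           config$rkm$threshold, ")", call. = FALSE)
    }
    rkm_split <- list(train = filt$retained, test = baseline_split$test)
  }
  rkm_scores <- tryCatch(
    train_and_score(rkm_split$train, rkm_split$test, config$classifiers),
    error = function(e) stop("filtered classification stage: ",
                             conditionMessage(e), call. = FALSE))

  structure(
    list(partition_counts = c(
           n_lower = part$n_objects - length(ambiguous_indices(part)),
           n_boundary = length(ambiguous_indices(part))),
         baseline = baseline, rkm = rkm_scores,
         excluded_rows = filt$ambiguous$row_indices,
         partition = part, config = config),
    class = "experiment_report"
  )
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Paired classification experiment\n")
  cat(sprintf("  rough partition: %d lower / %d boundary (filter stage: %s)\n",
              x$partition_counts["n_lower"], x$partition_counts["n_boundary"],
              x$config$filter_stage))
  for (m in names(x$baseline)) {
    b <- x$baseline[[m]]$metrics$accuracy
    r <- x$rkm[[m]]$metrics$accuracy
    cat(sprintf("  %-14s baseline %6.2f%%  filtered %6.2f%%  (%+.2f)\n",
                m, b, r, r - b))
  }
  invisible(x)
}

#' Tabulate an experiment report
#'
#' @param report An `"experiment_report"`.
#' @return Data frame with one row per (arm, classifier) and the five
#'   metrics, ready to write as CSV.
#' @export
report_table <- function(report) {
  rows <- list()
  for (arm in c("baseline", "rkm")) {
    for (m in names(report[[arm]])) {
      rows[[length(rows) + 1]] <- metrics_row(
        report[[arm]][[m]]$metrics, arm = arm, method = m,
        n_train = report[[arm]][[m]]$n_train,
        n_test = report[[arm]][[m]]$n_test)
    }
  }
  do.call(rbind, rows)
}

#' Write an experiment report to disk
#'
#' Emits `report.json` (full report: partition counts, per-arm confusion
#' counts and metrics, excluded rows, config echo), `metrics.csv` (the
#' [report_table()]), and `excluded_rows.csv`.
#'
#' @param report An `"experiment_report"`.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  arm_json <- function(arm) {
    lapply(report[[arm]], function(r) {
      list(counts = unclass(r$counts),
           metrics = r$metrics[c("accuracy", "sensitivity", "specificity",
                                 "precision", "f1")],
           n_train = r$n_train, n_test = r$n_test)
    })
  }
  jsonlite::write_json(
    list(partition_counts = as.list(report$partition_counts),
         baseline = arm_json("baseline"), rkm = arm_json("rkm"),
         excluded_rows = report$excluded_rows,
         filter_stage = report$config$filter_stage,
         split_fraction = report$config$split_fraction,
         split_seed = report$config$split_seed,
         rkm_params = unclass(report$config$rkm)),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(report_table(report), file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(excluded_row = report$excluded_rows),
                   file.path(dir, "excluded_rows.csv"), row.names = FALSE)
  invisible(dir)
}

#' Compare a fitted partition against reference lower/upper counts
#'
#' Quantifies how far a rough partition's lower-approximation and
#' boundary sizes are from a published reference split, as an absolute
#' count distance. Cluster-count reproduction on public tables depends on
#' unreported preprocessing and initialization, so this is a reporting
#' tool, not a pass/fail check.
#'
#' @param partition A `"rough_partition"`.
#' @param reference_lower,reference_upper Reference counts (lower
#'   approximation, boundary/upper-excluded).
#' @return List with the observed counts, the reference, and `distance`
#'   (`|lower - ref_lower|`, equal to `|boundary - ref_upper|` when totals
#'   match).
#' @export
reproduction_distance <- function(partition, reference_lower,
                                  reference_upper) {
  n_boundary <- length(ambiguous_indices(partition))
  n_lower <- partition$n_objects - n_boundary
  list(n_lower = n_lower, n_boundary = n_boundary,
       reference_lower = reference_lower, reference_upper = reference_upper,
       distance = abs(n_lower - reference_lower))
}

#' Serialize a rough partition to JSON
#'
#' Writes `{"centroids": [[...]], "lower": [[...]], "boundary": [[...]]}`
#' with 0-based row indices referring to the input row order after
#' preprocessing.
#'
#' @param partition A `"rough_partition"`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_partition_json <- function(partition, path) {
  jsonlite::write_json(
    list(
      centroids = apply(partition$centroids, 1, identity, simplify = FALSE),
      lower = lapply(partition$lower, function(ix) ix - 1L),
      boundary = lapply(partition$boundary, function(ix) ix - 1L),
      n_objects = partition$n_objects
    ),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
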