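# Known chronic-disease CSV schemas: expected feature count, label values
# and which label counts as "disease present".
.schemas <- list(
  diabetes = list(n_features = 8, positive = "1",
                  label_values = c("0", "1"), label_default = "class"),
  cancer   = list(n_features = 30, positive = "M",
                  label_values = c("B", "M"), label_default = "diagnosis"),
  kidney   = list(n_features = 24, positive = "ckd",
                  label_values = c("ckd", "notckd"), label_default = "class"),
  generic  = list(n_features = NA, positive = NULL, label_values = NULL,
                  label_default = NULL)
)

new_disease_dataset <- function(X, y, feature_names, positive_label,
                                provenance, feature_types = NULL,
                                row_indices = NULL) {
  stopifnot(length(y) == nrow(X))
  structure(
    list(X = X, y = as.integer(y), feature_names = feature_names,
         positive_label = positive_label, provenance = provenance,
         feature_types = feature_types,
         row_indices = if (is.null(row_indices)) seq_len(nrow(X))
                       else as.integer(row_indices)),
    class = "disease_dataset"
  )
}

#' @export
print.disease_dataset <- function(x, ...) {
  cat(sprintf("Disease dataset: %d records, %d features (%s)\n",
              nrow(x$X), length(x$feature_names),
              if (is.numeric(as.matrix(x$X))) "numeric" else "mixed"))
  cat(sprintf("  classes: %d positive ('%s'), %d negative\n",
              sum(x$y == 1), x$positive_label, sum(x$y == 0)))
  cat(sprintf("  provenance: %s\n", x$provenance))
  invisible(x)
}

#' Number of records in a dataset
#' @param dataset A `"disease_dataset"`.
#' @return Integer row count.
#' @export
n_records <- function(dataset) nrow(dataset$X)

#' Load a tabular disease dataset from CSV
#'
#' Reads a comma-separated table with a header row, validates it against a
#' named schema, normalizes the missing-value markers `"?"`, `""` and
#' `"NaN"` to `NA`, and maps the binary class column to 0/1 with the
#' disease-present level coded 1. The three named schemas cover the common
#' chronic-disease benchmark tables: `diabetes` (8 numeric features, class
#' 0/1 with 1 = diabetic), `cancer` (30 numeric features, diagnosis B/M
#' with M = malignant positive) and `kidney` (24 mixed numeric/nominal
#' features, class ckd/notckd with ckd positive). Use `generic` with an
#' explicit `label_column` for any other binary-class table.
#'
#' Rows are preserved in file order; no preprocessing is performed here
#' (see [preprocess_dataset()]).
#'
#' @param path Path to a CSV file.
#' @param schema One of `"generic"`, `"diabetes"`, `"kidney"`, `"cancer"`.
#' @param label_column Name of the class column. Required for `generic`;
#'   defaults to the schema's conventional name otherwise.
#' @param positive_label For `generic`: the level coded as 1 (default: the
#'   level sorting last).
#' @return A raw `"disease_dataset"` whose `X` is a data frame possibly
#'   holding nominal columns and missing values, with `feature_types`
#'   recording `"numeric"`/`"nominal"` per column.
#' @export
load_dataset <- function(path,
                         schema = c("generic", "diabetes", "kidney", "cancer"),
                         label_column = NULL, positive_label = NULL) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  spec <- .schemas[[schema]]
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("?", "", "NaN", "NA"),
                        strip.white = TRUE, check.names = FALSE)
  if (is.null(label_column)) label_column <- spec$label_default
  if (is.null(label_column)) {
    stop("`label_column` is required for the generic schema")
  }
  if (!label_column %in% names(df)) {
    stop("label column '", label_column, "' not found; columns present: ",
         paste(names(df), collapse = ", "))
  }
  feats <- df[setdiff(names(df), label_column)]
  if (!is.na(spec$n_features) && ncol(feats) != spec$n_features) {
    stop("schema '", schema, "' expects ", spec$n_features,
         " feature columns plus '", label_column, "', found ",
         ncol(feats), ": ", paste(names(feats), collapse = ", "))
  }
  lab <- trimws(as.character(df[[label_column]]))
  if (any(is.na(lab))) stop("missing values in the label column")
  levs <- sort(unique(lab))
  if (length(levs) != 2) {
    stop("class column must be binary; found levels: ",
         paste(levs, collapse = ", "))
  }
  if (!is.null(spec$label_values)) {
    unknown <- setdiff(levs, spec$label_values)
    if (length(unknown) > 0) {
      stop("unknown label value(s) for schema '", schema, "': ",
           paste(unknown, collapse = ", "), " (expected ",
           paste(spec$label_values, collapse = "/"), ")")
    }
    pos <- spec$positive
  } else {
    pos <- if (is.null(positive_label)) levs[2] else as.character(positive_label)
    if (!pos %in% levs) stop("positive label '", pos, "' not among levels")
  }
  types <- vapply(feats, function(col) {
    if (is.numeric(col)) "numeric" else "nominal"
  }, character(1))
  new_disease_dataset(
    X = feats, y = as.integer(lab == pos),
    feature_names = names(feats), positive_label = pos,
    provenance = paste0(schema, ":", path), feature_types = types
  )
}

#' Preprocessing configuration
#'
#' @param impute_numeric `"median"` or `"mean"` imputation for numeric
#'   columns.
#' @param impute_nominal Nominal imputation (`"mode"`).
#' @param encode_nominal `"integer"` maps a binary nominal column to 0/1
#'   (levels in sorted order) and one-hot encodes columns with more than
#'   two levels; `"one-hot"` one-hot encodes every nominal column.
#' @param scale `"minmax"` (to \[0, 1\]), `"zscore"`, or `"none"`.
#' @return A list of class `"preprocess_config"`.
#' @export
preprocess_config <- function(impute_numeric = c("median", "mean"),
                              impute_nominal = "mode",
                              encode_nominal = c("integer", "one-hot"),
                              scale = c("minmax", "zscore", "none")) {
  structure(
    list(impute_numeric = match.arg(impute_numeric),
         impute_nominal = match.arg(impute_nominal, "mode"),
         encode_nominal = match.arg(encode_nominal),
         scale = match.arg(scale)),
    class = "preprocess_config"
  )
}

stat_mode <- function(x) {
  x <- x[!is.na(x)]
  tab <- sort(table(x), decreasing = TRUE)
  names(tab)[1]
}

#' Impute, encode and scale a raw dataset
#'
#' Turns a raw [load_dataset()] result into the fully numeric, finite
#' feature matrix every downstream stage (rough K-means, classifiers)
#' consumes. Missing numerics are imputed by the column median (or mean),
#' missing nominals by the column mode; binary nominal columns become 0/1
#' integers and multi-level ones are one-hot encoded; numeric columns are
#' min-max scaled to \[0, 1\] by default. Row order and row count are never
#' altered — excluding rows is exclusively the ambiguity filter's job.
#'
#' The transformation parameters actually used (imputation values, level
#' maps, scaling ranges) are returned in the `"preprocess_params"`
#' attribute so they can be reapplied to held-out data via the `params`
#' argument.
#'
#' @param dataset A raw `"disease_dataset"`.
#' @param config A [preprocess_config()].
#' @param params Optional `"preprocess_params"` from a previous call;
#'   when supplied, those learned parameters are reapplied instead of being
#'   re-estimated (e.g. scale test data with training ranges).
#' @return A `"disease_dataset"` whose `X` is a numeric matrix with no
#'   missing entries, carrying attribute `"preprocess_params"`.
#' @export
preprocess_dataset <- function(dataset, config = preprocess_config(),
                               params = NULL) {
  X <- dataset$X
  if (is.matrix(X)) X <- as.data.frame(X)
  learn <- is.null(params)
  if (learn) {
    params <- list(config = config, columns = list())
  }
  out_cols <- list()
  for (name in names(X)) {
    col <- X[[name]]
    if (is.numeric(col)) {
      if (learn) {
        if (all(is.na(col))) stop("column '", name, "' is entirely missing")
        fill <- if (config$impute_numeric == "median") {
          stats::median(col, na.rm = TRUE)
        } else {
          mean(col, na.rm = TRUE)
        }
        rng <- range(col, na.rm = TRUE)
        params$columns[[name]] <- list(kind = "numeric", fill = fill,
                                       min = rng[1], max = rng[2],
                                       mean = mean(col, na.rm = TRUE),
                                       sd = stats::sd(col, na.rm = TRUE))
      }
      p <- params$columns[[name]]
      col[is.na(col)] <- p$fill
      col <- switch(params$config$scale,
        minmax = if (p$max > p$min) (col - p$min) / (p$max - p$min)
                 else col * 0,
        zscore = if (!is.na(p$sd) && p$sd > 0) (col - p$mean) / p$sd
                 else col * 0,
        none = col)
      out_cols[[name]] <- col
    } else {
      col <- trimws(as.character(col))
      col[col == ""] <- NA
      if (learn) {
        if (all(is.na(col))) stop("column '", name, "' is entirely missing")
        levs <- sort(unique(col[!is.na(col)]))
        params$columns[[name]] <- list(kind = "nominal",
                                       fill = stat_mode(col), levels = levs)
      }
      p <- params$columns[[name]]
      col[is.na(col)] <- p$fill
      onehot <- params$config$encode_nominal == "one-hot" ||
        length(p$levels) > 2
      if (onehot) {
        for (lev in p$levels) {
          out_cols[[paste0(name, "=", lev)]] <- as.numeric(col == lev)
        }
      } else {
        # binary nominal: second sorted level codes as 1
        out_cols[[name]] <- as.numeric(col == p$levels[length(p$levels)])
      }
    }
  }
  Xnum <- do.call(cbind, out_cols)
  colnames(Xnum) <- names(out_cols)
  rownames(Xnum) <- NULL
  res <- new_disease_dataset(
    X = Xnum, y = dataset$y, feature_names = colnames(Xnum),
    positive_label = dataset$positive_label,
    provenance = paste0(dataset$provenance, " [preprocessed]"),
    feature_types = rep("numeric", ncol(Xnum)),
    row_indices = dataset$row_indices
  )
  attr(res, "preprocess_params") <- params
  res
}

#' Decode a nominal encoding back to its levels
#'
#' Inverse of the integer encoding of a binary nominal column, mainly for
#' checking that encoding is lossless.
#'
#' @param encoded Numeric 0/1 vector.
#' @param levels The two sorted original levels.
#' @return Character vector of original level values.
#' @export
decode_nominal <- function(encoded, levels) {
  stopifnot(length(levels) == 2)
  levels[encoded + 1]
}

#' Subset a dataset by row indices
#'
#' Keeps labels, names and provenance in sync; the retained original row
#' indices are tracked through `row_indices`.
#'
#' @param dataset A `"disease_dataset"`.
#' @param rows Integer row indices to keep.
#' @param tag Provenance suffix describing the subset.
#' @return The subsetted `"disease_dataset"`.
#' @export
subset_dataset <- function(dataset, rows, tag = "subset") {
  X <- dataset$X
  Xs <- if (is.data.frame(X)) X[rows, , drop = FALSE]
        else X[rows, , drop = FALSE]
  if (is.data.frame(Xs)) rownames(Xs) <- NULL else rownames(Xs) <- NULL
  new_disease_dataset(
    X = Xs, y = dataset$y[rows], feature_names = dataset$feature_names,
    positive_label = dataset$positive_label,
    provenance = paste0(dataset$provenance, " [", tag, "]"),
    feature_types = dataset$feature_types,
    row_indices = dataset$row_indices[rows]
  )
}

#' Write a dataset back to CSV
#'
#' @param dataset A `"disease_dataset"`.
#' @param path Output file path.
#' @param label_column Name for the class column (default `"class"`).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, label_column = "class") {
  df <- as.data.frame(dataset$X)
  df[[label_column]] <- dataset$y
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
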