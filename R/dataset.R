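#' Construct an expression dataset
#'
#' The container every stage of the pipeline consumes and produces views of:
#' a numeric samples x features matrix, a binary class label per sample, and
#' unique sample/feature identifiers. Missing measurements are `NA` (never 0:
#' zero is a valid expression value).
#'
#' Labels are stored as a two-level factor. Unless `positive_class` is given,
#' the first class in lexicographic order becomes the negative class and the
#' second the positive (disease/tumor) class, so the mapping is deterministic
#' without external metadata.
#'
#' @param values numeric matrix, samples in rows, features in columns.
#' @param labels vector of class labels, one per sample (exactly two distinct
#'   values for any operation that needs classes).
#' @param feature_ids character vector of feature identifiers. Duplicates are
#'   tolerated (they are resolved by [average_duplicate_features()]).
#' @param sample_ids character vector of unique sample identifiers.
#' @param positive_class optional label value to treat as the positive class.
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `values`, `labels` (factor, level 1 = negative, level 2 = positive),
#'   `feature_ids`, `sample_ids`.
#' @export
expression_dataset <- function(values, labels, feature_ids = NULL,
                               sample_ids = NULL, positive_class = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  p <- ncol(values)
  if (is.null(feature_ids)) {
    feature_ids <- colnames(values)
    if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(p))
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  }
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(labels) != n) {
    stop("length(labels) [", length(labels), "] != number of samples [", n, "]")
  }
  if (length(feature_ids) != p) {
    stop("length(feature_ids) != number of features")
  }
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  lv <- sort(unique(as.character(labels)))
  if (!is.null(positive_class)) {
    positive_class <- as.character(positive_class)
    if (!positive_class %in% lv) {
      stop("positive_class '", positive_class, "' not among labels")
    }
    lv <- c(setdiff(lv, positive_class), positive_class)
  }
  labels <- factor(as.character(labels), levels = lv)
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(
    list(values = values, labels = labels,
         feature_ids = feature_ids, sample_ids = sample_ids),
    class = "ExpressionDataset"
  )
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat("ExpressionDataset: ", nrow(x$values), " samples x ",
      ncol(x$values), " features\n", sep = "")
  cat("classes: ", paste(levels(x$labels), collapse = " / "),
      "  (", paste(tabulate(x$labels, length(levels(x$labels))),
                   collapse = "/"), ")\n", sep = "")
  nmiss <- sum(is.na(x$values))
  if (nmiss > 0) cat("missing cells: ", nmiss, "\n", sep = "")
  invisible(x)
}

n_samples <- function(ds) nrow(ds$values)
n_features <- function(ds) ncol(ds$values)

# indices of positive (level 2) / negative (level 1) samples
positive_idx <- function(ds) which(as.integer(ds$labels) == 2L)
negative_idx <- function(ds) which(as.integer(ds$labels) == 1L)

check_two_classes <- function(ds) {
  k <- length(unique(as.integer(ds$labels[!is.na(ds$labels)])))
  if (k != 2L) {
    stop("exactly two classes are required, found ", k)
  }
  invisible(TRUE)
}

#' Restrict a dataset to a subset of features
#'
#' @param ds an `ExpressionDataset`.
#' @param features integer indices or feature identifiers.
#' @return An `ExpressionDataset` view holding only the requested features.
#' @export
subset_features <- function(ds, features) {
  if (is.character(features)) {
    features <- match(features, ds$feature_ids)
    if (anyNA(features)) stop("unknown feature id(s)")
  }
  expression_dataset(ds$values[, features, drop = FALSE],
                     labels = as.character(ds$labels),
                     feature_ids = ds$feature_ids[features],
                     sample_ids = ds$sample_ids,
                     positive_class = levels(ds$labels)[2L])
}

#' Read a labeled expression matrix from delimited text
#'
#' Reads a CSV/TSV file into an [expression_dataset()]. Two layouts are
#' supported: `features_in_columns` (one row per sample; one column holds the
#' class label; an optional first unnamed column holds sample ids) and
#' `features_in_rows` (one row per feature, one column per sample; one row —
#' named in `label_field` — holds the class labels). Empty cells and the
#' strings `NA`, `NaN`, `null` are read as missing values, never as zero.
#'
#' @param path path to a delimited text file with a header.
#' @param orientation `"features_in_columns"` (default) or
#'   `"features_in_rows"`.
#' @param label_field name of the label column (or, for `features_in_rows`,
#'   the label row's identifier in the first column). Default `"label"`.
#' @param sep field separator; inferred from the file extension by default
#'   (`.tsv`/`.txt` gives tab, otherwise comma).
#' @param positive_class optional label value to use as the positive class;
#'   by default the lexicographically larger label is positive.
#' @return An `ExpressionDataset`.
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("features_in_columns",
                                                   "features_in_rows"),
                                   label_field = "label",
                                   sep = NULL,
                                   positive_class = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      stringsAsFactors = FALSE, na.strings = c("", "NA", "NaN", "null"),
                      quote = "\"", comment.char = ""),
    error = function(e) stop("failed to parse '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (orientation == "features_in_columns") {
    if (!label_field %in% names(df)) {
      stop("label column '", label_field, "' not found in ", path)
    }
    labels <- as.character(df[[label_field]])
    df[[label_field]] <- NULL
    # a leading non-numeric id column becomes the sample ids
    sample_ids <- NULL
    if (ncol(df) > 0) {
      first <- df[[1L]]
      if (is.character(first) && anyNA(suppressWarnings(as.numeric(first[!is.na(first)])))) {
        sample_ids <- as.character(first)
        df[[1L]] <- NULL
      }
    }
    values <- parse_numeric_frame(df, path)
    if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(values)))
    feature_ids <- colnames(values)
  } else {
    row_ids <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
    lab_row <- which(row_ids == label_field)
    if (length(lab_row) != 1L) {
      stop("label row '", label_field, "' not found (or duplicated) in ", path)
    }
    labels <- as.character(unlist(df[lab_row, ], use.names = FALSE))
    feature_ids <- row_ids[-lab_row]
    values <- t(parse_numeric_frame(df[-lab_row, , drop = FALSE], path))
    colnames(values) <- feature_ids
    sample_ids <- names(df)
  }
  if (anyNA(labels)) stop("missing class label(s) in ", path)
  if (length(unique(labels)) < 2L) {
    stop("fewer than 2 classes in ", path)
  }
  expression_dataset(values, labels, feature_ids = feature_ids,
                     sample_ids = sample_ids, positive_class = positive_class)
}

parse_numeric_frame <- function(df, path) {
  m <- matrix(NA_real_, nrow(df), ncol(df),
              dimnames = list(NULL, names(df)))
  for (j in seq_along(df)) {
    col <- df[[j]]
    if (is.numeric(col)) {
      m[, j] <- as.double(col)
    } else {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))
      if (length(bad) > 0) {
        stop("non-numeric cell in '", path, "', column '", names(df)[j],
             "', data line ", bad[1L])
      }
      m[, j] <- num
    }
  }
  m
}

#' Write an expression dataset as CSV
#'
#' Inverse of [read_expression_matrix()] for the `features_in_columns`
#' layout; full-precision numeric formatting so a read/write/read round trip
#' is value-identical.
#'
#' @param ds an `ExpressionDataset`.
#' @param path output file path.
#' @param label_field name for the label column.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(ds, path, label_field = "label") {
  df <- data.frame(sample_id = ds$sample_ids,
                   label = as.character(ds$labels),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[2L] <- label_field
  vals <- as.data.frame(ds$values, check.names = FALSE)
  # 17 significant digits: lossless for doubles
  vals[] <- lapply(vals, function(v) ifelse(is.na(v), NA, sprintf("%.17g", v)))
  df <- cbind(df, vals)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}
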