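#' Construct a tabular dataset for forest analysis
#'
#' Bundles a numeric feature matrix and an outcome vector together with the
#' prediction task. All downstream operations (forest training, VIMP, the
#' residual-VIMP test) act on this container.
#'
#' @param features Numeric matrix or data frame, `n` rows by `p` columns, with
#'   column names. No missing values allowed.
#' @param outcome Numeric vector of length `n`. Continuous for
#'   `task = "regression"`; exactly the values 0/1 for
#'   `task = "classification"`.
#' @param task `"regression"` or `"classification"`.
#' @return An object of class `"tabular_dataset"`: a list with elements
#'   `features` (numeric matrix), `outcome` (numeric vector) and `task`.
#' @examples
#' x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
#' d <- tabular_dataset(x, rnorm(20), "regression")
#' d
#' @export
tabular_dataset <- function(features, outcome, task = c("regression", "classification")) {
  task <- match.arg(task)
  if (is.data.frame(features)) features <- as.matrix(features)
  if (!is.matrix(features) || !is.numeric(features)) {
    stop("`features` must be a numeric matrix or data frame", call. = FALSE)
  }
  if (is.null(colnames(features)) || anyDuplicated(colnames(features))) {
    stop("`features` must have unique column names", call. = FALSE)
  }
  if (!is.numeric(outcome)) stop("`outcome` must be numeric", call. = FALSE)
  n <- nrow(features)
  if (length(outcome) != n) {
    stop("`outcome` length (", length(outcome), ") does not match number of rows (",
         n, ")", call. = FALSE)
  }
  if (n < 2L) stop("at least 2 rows are required", call. = FALSE)
  if (ncol(features) < 1L) stop("at least 1 feature is required", call. = FALSE)
  if (anyNA(features) || anyNA(outcome)) {
    stop("missing values are not supported; impute or drop them first", call. = FALSE)
  }
  if (task == "classification" && !all(outcome %in% c(0, 1))) {
    stop("classification outcome must take exactly the values 0 and 1", call. = FALSE)
  }
  structure(list(features = features, outcome = as.numeric(outcome), task = task),
            class = "tabular_dataset")
}

#' @export
print.tabular_dataset <- function(x, ...) {
  cat("<tabular_dataset> ", nrow(x$features), " obs. x ", ncol(x$features),
      " features (", x$task, ")\n", sep = "")
  cat("  features:", paste(head(colnames(x$features), 8), collapse = ", "),
      if (ncol(x$features) > 8) "...", "\n")
  invisible(x)
}

#' Read a dataset from delimited text
#'
#' Reads a CSV or TSV file with a header row, designates one column as the
#' outcome, and returns a [tabular_dataset()]. All remaining columns become
#' features and must be numeric.
#'
#' @param path Path to the file. Files ending in `.tsv` / `.txt` are read as
#'   tab-separated, anything else as comma-separated; override with `sep`.
#' @param outcome Name of the outcome column.
#' @param task Prediction task, see [tabular_dataset()].
#' @param sep Optional field separator overriding the extension-based guess.
#' @return A `"tabular_dataset"`.
#' @export
read_dataset <- function(path, outcome, task = c("regression", "classification"),
                         sep = NULL) {
  task <- match.arg(task)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- read.csv(path, sep = sep, header = TRUE, check.names = FALSE)
  if (!outcome %in% names(df)) {
    stop("outcome column '", outcome, "' not found in ", path, call. = FALSE)
  }
  y <- df[[outcome]]
  x <- df[setdiff(names(df), outcome)]
  if (!all(vapply(x, is.numeric, logical(1)))) {
    bad <- names(x)[!vapply(x, is.numeric, logical(1))]
    stop("non-numeric feature column(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  tabular_dataset(as.matrix(x), y, task)
}

# Internal: replace one feature column (used to swap Z for its residuals).
#' @noRd
replace_feature <- function(data, feature, values) {
  j <- match_feature(data, feature)
  data$features[, j] <- values
  data
}

#' @noRd
match_feature <- function(data, feature) {
  nm <- colnames(data$features)
  if (is.character(feature)) {
    j <- match(feature, nm)
    if (is.na(j)) stop("feature '", feature, "' not found", call. = FALSE)
  } else {
    j <- as.integer(feature)
    if (is.na(j) || j < 1L || j > length(nm)) {
      stop("feature index out of range", call. = FALSE)
    }
  }
  j
}

# Internal: dataset restricted to a row subset.
#' @noRd
subset_rows <- function(data, rows) {
  structure(list(features = data$features[rows, , drop = FALSE],
                 outcome = data$outcome[rows], task = data$task),
            class = "tabular_dataset")
}
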