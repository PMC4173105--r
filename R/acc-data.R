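#' Construct an analysis dataset with a partially observed covariate block
#'
#' Validates subject-level data for augmented complete-case analysis: an
#' outcome `Y`, fully observed covariates `Z`, and a covariate block `X` in
#' which, for any given subject, either every component is observed or every
#' component is missing. The observation indicator `R` (1 = X observed) is
#' derived from the missingness pattern of the X columns.
#'
#' @param data A data frame with one row per subject.
#' @param outcome Name of the outcome column (single string).
#' @param x_cols Character vector of partially observed covariate columns.
#'   Missing entries must be `NA` (use [read_acc_csv()] to map sentinels).
#' @param z_cols Character vector of fully observed covariate columns
#'   (may be empty).
#' @param ids Optional vector of subject labels (defaults to row order).
#'
#' @return An object of class `acc_data`: a list with components `y` (length
#'   n), `x` (n x p matrix, `NA` where unobserved), `z` (n x q matrix), `r`
#'   (integer 0/1 vector), `ids`, and dimensions `n`, `p`, `q`. Rows with a
#'   *partially* missing X block, or any missing Y or Z value, are rejected
#'   with a row-indexed error: such rows must be resolved by the analyst, not
#'   silently dropped.
#' @examples
#' df <- data.frame(Y = rnorm(6), X = c(1, NA, 3, NA, 5, 6), Z = rnorm(6))
#' d <- acc_data(df, outcome = "Y", x_cols = "X", z_cols = "Z")
#' d$r
#' @export
acc_data <- function(data, outcome, x_cols, z_cols = character(), ids = NULL) {
  stopifnot(is.data.frame(data), nrow(data) >= 1)
  cols <- c(outcome, x_cols, z_cols)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    stop("column(s) not found in data: ", paste(missing_cols, collapse = ", "))
  }
  if (length(outcome) != 1) stop("exactly one outcome column is required")
  if (length(intersect(x_cols, z_cols)) > 0) {
    stop("x_cols and z_cols must be disjoint")
  }
  if (length(x_cols) < 1) stop("at least one partially observed X column is required")

  num <- function(col) {
    v <- data[[col]]
    if (!is.numeric(v)) stop("column '", col, "' is not numeric")
    as.numeric(v)
  }
  y <- num(outcome)
  if (anyNA(y)) {
    stop("missing outcome value in row(s) ",
         paste(which(is.na(y)), collapse = ", "),
         "; rows with missing Y must be removed by the user before analysis")
  }
  z <- if (length(z_cols) > 0) {
    zm <- vapply(z_cols, num, numeric(nrow(data)))
    dim(zm) <- c(nrow(data), length(z_cols))
    colnames(zm) <- z_cols
    na_rows <- which(rowSums(is.na(zm)) > 0)
    if (length(na_rows) > 0) {
      bad <- z_cols[which(is.na(zm[na_rows[1], ]))[1]]
      stop("missing value in fully observed covariate '", bad, "' at row(s) ",
           paste(na_rows, collapse = ", "),
           "; rows with missing Z must be removed by the user before analysis")
    }
    zm
  } else {
    matrix(numeric(0), nrow = nrow(data), ncol = 0)
  }
  x <- vapply(x_cols, num, numeric(nrow(data)))
  dim(x) <- c(nrow(data), length(x_cols))
  colnames(x) <- x_cols
  n_miss <- rowSums(is.na(x))
  partial <- which(n_miss > 0 & n_miss < ncol(x))
  if (length(partial) > 0) {
    stop("partially missing X block at row(s) ",
         paste(partial, collapse = ", "),
         ": each subject must have the X block fully observed or fully missing")
  }
  r <- as.integer(n_miss == 0)
  if (sum(r) < 1) stop("no complete cases: at least one subject must have X observed")

  structure(
    list(
      y = y, x = x, z = z, r = r,
      ids = if (is.null(ids)) seq_len(nrow(data)) else ids,
      n = nrow(data), p = ncol(x), q = ncol(z)
    ),
    class = "acc_data"
  )
}

#' @export
print.acc_data <- function(x, ...) {
  cat("<acc_data> n =", x$n, "subjects; p =", x$p, "partially observed,",
      "q =", x$q, "fully observed covariate(s);",
      sum(x$r), sprintf("complete cases (%.1f%%)\n", 100 * mean(x$r)))
  invisible(x)
}

#' @export
#' @exportS3Method tibble::as_tibble
as_tibble.acc_data <- function(x, ...) {
  out <- tibble::tibble(.id = x$ids, y = x$y)
  for (j in seq_len(x$p)) out[[colnames(x$x)[j]]] <- x$x[, j]
  for (j in seq_len(x$q)) out[[colnames(x$z)[j]]] <- x$z[, j]
  out$.r <- x$r
  out
}

# internal: complete-case row indices
cc_idx <- function(data) which(data$r == 1L)

#' Read an analysis dataset from CSV
#'
#' Reads a comma-separated file with a header row and builds an [acc_data()]
#' object. Missing entries of the X block may be empty fields or a sentinel
#' string (default `"NA"`); the dialect is fixed (comma separator, `.`
#' decimal, UTF-8).
#'
#' @param path Path to the CSV file.
#' @inheritParams acc_data
#' @param sentinel String marking a missing X entry, in addition to empty
#'   fields.
#' @return An `acc_data` object.
#' @export
read_acc_csv <- function(path, outcome, x_cols, z_cols = character(),
                         sentinel = "NA") {
  df <- utils::read.csv(path, header = TRUE, na.strings = c("", sentinel),
                        fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  acc_data(df, outcome = outcome, x_cols = x_cols, z_cols = z_cols)
}
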