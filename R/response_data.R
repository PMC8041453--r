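#' Binary response data for two groups of test takers
#'
#' Validates and bundles a persons-by-items matrix of dichotomous responses
#' together with a two-level group label (reference and focal group). This is
#' the raw input of the whole DIF pipeline. Missing values and non-binary
#' entries are rejected outright.
#'
#' @param responses matrix or data frame of 0/1 responses, one row per person,
#'   one column per item (\eqn{m \ge 2}). Column names are kept as item labels;
#'   unnamed columns are labelled \code{Item1, ..., Itemm}.
#' @param group vector of length \code{nrow(responses)} with exactly two
#'   distinct values; coerced to a factor whose first level is the reference
#'   group.
#' @return An object of class \code{"response_data"}: a list with components
#'   \code{responses} (integer matrix) and \code{group} (factor).
#' @seealso [read_responses()] to load from delimited text,
#'   [generate_response()] to simulate.
#' @export
response_data <- function(responses, group) {
  x <- as.matrix(responses)
  if (is.data.frame(responses)) x <- data.matrix(responses)
  storage.mode(x) <- "double"
  if (anyNA(x)) {
    idx <- which(is.na(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value in responses at row %d, column %d; missing data are not supported",
                 idx[1L], idx[2L]))
  }
  bad <- which(!(x %in% c(0, 1)))
  if (length(bad)) {
    idx <- arrayInd(bad[1L], dim(x))
    stop(sprintf("non-binary entry '%s' in responses at row %d, column %d (values must be 0 or 1)",
                 format(x[bad[1L]]), idx[1L], idx[2L]))
  }
  if (ncol(x) < 2L) stop("at least 2 items are required")
  if (length(group) != nrow(x))
    stop("length of 'group' (", length(group), ") must equal the number of persons (",
         nrow(x), ")")
  g <- factor(group)
  if (nlevels(g) != 2L)
    stop("'group' must have exactly two levels, found ", nlevels(g), ": ",
         paste(levels(g), collapse = ", "))
  if (is.null(colnames(x))) colnames(x) <- paste0("Item", seq_len(ncol(x)))
  storage.mode(x) <- "integer"
  structure(list(responses = x, group = g), class = "response_data")
}

#' @export
print.response_data <- function(x, ...) {
  cat("Binary response data:", nrow(x$responses), "persons,",
      ncol(x$responses), "items\n")
  cat("Groups:", paste(sprintf("%s (n = %d)", levels(x$group),
                               tabulate(x$group, 2L)), collapse = ", "), "\n")
  invisible(x)
}

# split a response_data object into the two per-group matrices
split_groups <- function(data) {
  stopifnot(inherits(data, "response_data"))
  lapply(split(seq_along(data$group), data$group),
         function(i) data$responses[i, , drop = FALSE])
}
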