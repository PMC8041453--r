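#' Read a wide-format response matrix from delimited text
#'
#' Reads a CSV or TSV file with one row per person, one column per item
#' (values strictly 0/1) and one group column with exactly two levels.
#' Validation failures are reported with row and column references.
#'
#' @param path path to the file; \code{.csv} is read comma-separated,
#'   anything else tab-separated (override with \code{sep}).
#' @param group_column name of the group column (default \code{"group"}).
#' @param sep field separator; inferred from the extension when \code{NULL}.
#' @return A [response_data] object; item column names are preserved.
#' @export
read_responses <- function(path, group_column = "group", sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!group_column %in% names(df))
    stop("group column '", group_column, "' not found in ", path,
         " (columns: ", paste(names(df), collapse = ", "), ")")
  group <- df[[group_column]]
  items <- df[setdiff(names(df), group_column)]
  for (j in seq_along(items)) {
    v <- items[[j]]
    bad <- which(is.na(v) | !(v %in% c(0, 1)))
    if (length(bad))
      stop(sprintf("column '%s', row %d: value '%s' is not 0 or 1",
                   names(items)[j], bad[1L], as.character(v[bad[1L]])))
  }
  g <- factor(group)
  if (nlevels(g) != 2L)
    stop("group column '", group_column, "' must have exactly two levels, found ",
         nlevels(g), ": ", paste(levels(g), collapse = ", "))
  response_data(as.matrix(items), g)
}

# numeric columns formatted so that values round-trip exactly through text
format_full <- function(df) {
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  df
}

write_tsv <- function(df, file) {
  utils::write.table(format_full(df), file = file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

#' Export a criterion curve
#'
#' Writes the plotting grid as tab-separated text (columns \code{shift},
#' \code{gini}, \code{clf}; full precision) or the structured results
#' (candidates with criterion values, global and local optima, search
#' interval) as JSON.
#'
#' @param curve a [criterion_curve()] object.
#' @param file output path.
#' @param format \code{"tsv"} (grid) or \code{"json"} (candidates and optima).
#' @return \code{file}, invisibly.
#' @export
write_criterion_curve <- function(curve, file, format = c("tsv", "json")) {
  stopifnot(inherits(curve, "criterion_curve"))
  format <- match.arg(format)
  if (format == "tsv") {
    write_tsv(curve$grid, file)
  } else {
    jsonlite::write_json(list(
      interval = curve$interval,
      criterion = curve$criterion,
      shift = curve$shift,
      candidates = curve$candidates,
      global = curve$global,
      local = curve$local), file, auto_unbox = TRUE, digits = NA)
  }
  invisible(file)
}

#' Export a DIF table
#'
#' Writes the per-item Wald test results as tab-separated text or JSON,
#' including the shift (and anchor set, if any) and the significance level.
#'
#' @param tab a \code{"dif_table"} from [wald_test()] or
#'   [anchored_wald_test()].
#' @param file output path.
#' @param format \code{"tsv"} or \code{"json"}.
#' @return \code{file}, invisibly.
#' @export
write_dif_table <- function(tab, file, format = c("tsv", "json")) {
  stopifnot(inherits(tab, "dif_table"))
  format <- match.arg(format)
  if (format == "tsv") {
    write_tsv(as.data.frame(tab), file)
  } else {
    jsonlite::write_json(list(
      shift = attr(tab, "shift"), anchor = attr(tab, "anchor"),
      alpha = attr(tab, "alpha"), adjust = attr(tab, "adjust"),
      items = as.data.frame(tab)), file, auto_unbox = TRUE, digits = NA)
  }
  invisible(file)
}

#' Export an anchor selection
#'
#' @param sel an \code{"anchor_selection"} object.
#' @param file output path (JSON).
#' @return \code{file}, invisibly.
#' @export
write_anchor_selection <- function(sel, file) {
  stopifnot(inherits(sel, "anchor_selection"))
  jsonlite::write_json(unclass(sel), file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Serialize a simulation design or result
#'
#' \code{write_sim_design()}/\code{read_sim_design()} round-trip a
#' [sim_design()] through JSON (used e.g. to drive the command-line
#' interface). \code{write_sim_result()} writes the aggregated rates table as
#' tab-separated text (rows: method; columns: rates and Monte-Carlo standard
#' errors) or, with metadata, as JSON.
#'
#' @param design a \code{"sim_design"}; \code{res} a \code{"sim_result"}.
#' @param file path.
#' @param format for results, \code{"tsv"} or \code{"json"}.
#' @return \code{file} (writers, invisibly) or the restored object (reader).
#' @export
write_sim_design <- function(design, file) {
  stopifnot(inherits(design, "sim_design"))
  jsonlite::write_json(unclass(design), file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_sim_design
#' @export
read_sim_design <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  need <- setdiff(c("m", "n_ref", "n_foc"), names(x))
  if (length(need))
    stop("design file ", file, " is missing field(s): ",
         paste(need, collapse = ", "))
  x$dif_items <- as.integer(x$dif_items)
  do.call(sim_design, x[intersect(names(x), names(formals(sim_design)))])
}

#' @rdname write_sim_design
#' @param res a \code{"sim_result"} from [run_simulation()].
#' @export
write_sim_result <- function(res, file, format = c("tsv", "json")) {
  stopifnot(inherits(res, "sim_result"))
  format <- match.arg(format)
  if (format == "tsv") {
    write_tsv(as.data.frame(res), file)
  } else {
    jsonlite::write_json(list(
      design = unclass(attr(res, "design")), scoring = attr(res, "scoring"),
      alpha = attr(res, "alpha"), reps = attr(res, "reps"),
      failures = attr(res, "failures"), rates = as.data.frame(res)),
      file, auto_unbox = TRUE, digits = NA)
  }
  invisible(file)
}
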