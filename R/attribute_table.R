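#' Attribute table
#'
#' The tabular container consumed by training and classification: a numeric
#' matrix of continuous attribute values (one row per instance, `NA` marking a
#' missing cell), an optional class label per row, and optional identifier
#' columns passed through to result files untouched.
#'
#' @param x A data.frame (or numeric matrix) holding the attribute columns.
#' @param attributes Character vector naming the attribute columns; defaults
#'   to every column of `x` not named by `class_column`/`id_columns`.
#' @param class_column Optional name of the class-label column in `x`.
#' @param id_columns Optional names of identifier columns in `x`.
#' @return An object of class `attribute_table` with fields `values` (numeric
#'   matrix), `attribute_names`, `labels` (character or NULL), `ids`
#'   (data.frame or NULL).
#' @export
attribute_table <- function(x, attributes = NULL, class_column = NULL,
                            id_columns = NULL) {
  x <- as.data.frame(x, check.names = FALSE)
  if (anyDuplicated(names(x)))
    aode_stop("schema", "duplicate column names: ",
              paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  if (!is.null(class_column) && !class_column %in% names(x))
    aode_stop("schema", "class column '", class_column, "' not found")
  if (!is.null(id_columns) && !all(id_columns %in% names(x)))
    aode_stop("schema", "id column(s) not found: ",
              paste(setdiff(id_columns, names(x)), collapse = ", "))
  attributes <- attributes %||% setdiff(names(x), c(class_column, id_columns))
  if (!length(attributes)) aode_stop("schema", "no attribute columns")
  if (!all(attributes %in% names(x)))
    aode_stop("schema", "attribute column(s) not found: ",
              paste(setdiff(attributes, names(x)), collapse = ", "))
  if (!is.null(class_column) && class_column %in% attributes)
    aode_stop("schema", "class column must be distinct from attribute columns")
  vals <- as.matrix(x[attributes])
  if (!is.numeric(vals)) aode_stop("validation", "attribute columns must be numeric")
  storage.mode(vals) <- "double"
  if (any(!is.finite(vals[!is.na(vals)])))
    aode_stop("validation", "present attribute values must be finite")
  rownames(vals) <- NULL
  structure(
    list(values = vals,
         attribute_names = attributes,
         labels = if (!is.null(class_column)) as.character(x[[class_column]]),
         ids = if (!is.null(id_columns)) x[id_columns]),
    class = "attribute_table")
}

#' @export
print.attribute_table <- function(x, ...) {
  cat("attribute_table:", nrow(x$values), "instances,",
      length(x$attribute_names), "attributes (",
      paste(utils::head(x$attribute_names, 8L), collapse = ", "),
      if (length(x$attribute_names) > 8L) ", ..." else "", ")\n", sep = "")
  if (!is.null(x$labels)) {
    tb <- table(x$labels)
    cat("  classes:", paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "), "\n")
  }
  nm <- sum(is.na(x$values))
  cat("  missing cells:", nm, sprintf("(%.1f%%)", 100 * nm / length(x$values)), "\n")
  invisible(x)
}

#' @export
as.data.frame.attribute_table <- function(x, ...) {
  out <- as.data.frame(x$values)
  if (!is.null(x$ids)) out <- cbind(x$ids, out)
  if (!is.null(x$labels)) out$class <- x$labels
  out
}

#' Number of instances in an attribute table
#' @param table An [attribute_table()].
#' @return Integer row count.
#' @export
n_instances <- function(table) nrow(table$values)

sniff_sep <- function(path) {
  first <- readLines(path, n = 25L)
  first <- first[!startsWith(first, "#")]
  if (!length(first)) aode_stop("format", "empty file: ", path)
  if (grepl("\t", first[1L])) "\t" else ","
}

#' Read a delimited attribute table
#'
#' Reads a TSV/CSV file with a header row. The delimiter is sniffed from the
#' header (tab wins over comma) unless forced with `sep`. Cells matching a
#' missing marker (`"NA"`, empty, `"nan"`, case-insensitive by default)
#' become missing; every other attribute cell must parse as a number, and a
#' cell that does not is reported with its row and column.
#'
#' @param path File path.
#' @param class_column Optional name of the class-label column.
#' @param id_columns Optional identifier columns to pass through.
#' @param missing_markers Character vector of markers treated as missing.
#' @param sep Optional delimiter override ("\\t" or ",").
#' @return An [attribute_table()].
#' @export
read_table <- function(path, class_column = NULL, id_columns = NULL,
                       missing_markers = c("NA", "", "nan"), sep = NULL) {
  if (!file.exists(path)) aode_stop("input", "file not found: ", path)
  sep <- sep %||% sniff_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, colClasses = "character",
                           check.names = FALSE, comment.char = "#",
                           quote = "\"", na.strings = NULL, stringsAsFactors = FALSE)
  if (anyDuplicated(names(raw)))
    aode_stop("schema", "duplicate header column(s): ",
              paste(unique(names(raw)[duplicated(names(raw))]), collapse = ", "))
  attrs <- setdiff(names(raw), c(class_column, id_columns))
  markers <- tolower(missing_markers)
  parsed <- raw
  for (a in attrs) {
    cell <- raw[[a]]
    miss <- tolower(trimws(cell)) %in% markers
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!miss & is.na(num))
    if (length(bad))
      aode_stop("input", "cell '", cell[bad[1L]], "' in column '", a,
                "', row ", bad[1L], " is not numeric")
    num[miss] <- NA_real_
    parsed[[a]] <- num
  }
  attribute_table(parsed, attributes = attrs, class_column = class_column,
                  id_columns = id_columns)
}

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1L))
  out
}

#' Write an attribute table as TSV
#'
#' Numbers are written with 17 significant digits so that
#' `read_table(write_table(x))` round-trips values exactly.
#'
#' @param table An [attribute_table()].
#' @param path Output path.
#' @param class_column Name to use for the label column (default "class").
#' @return Invisibly, `path`.
#' @export
write_table <- function(table, path, class_column = "class") {
  stopifnot(inherits(table, "attribute_table"))
  df <- as.data.frame(lapply(as.data.frame(table$values), fmt_num),
                      check.names = FALSE)
  names(df) <- table$attribute_names
  if (!is.null(table$ids)) df <- cbind(table$ids, df)
  if (!is.null(table$labels)) df[[class_column]] <- table$labels
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
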