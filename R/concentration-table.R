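#' Per-site table of soil metal concentrations
#'
#' A `concentration_table` holds one site's analytical results: a numeric
#' matrix of samples (rows) by metals (columns), in mg/kg dry weight.
#' It is the raw input to [summarize()], [pearson_matrix()], [assess_site()]
#' and [run_simulation()].
#'
#' @param values Numeric matrix or data frame, samples x metals. All entries
#'   must be finite and non-negative.
#' @param site_id Character scalar naming the site.
#' @param sample_ids Optional character vector of unique sample labels;
#'   defaults to existing rownames or `S1..Sn`.
#' @param metals Optional character vector of unique metal symbols; defaults
#'   to the column names of `values`.
#'
#' @return An object of class `concentration_table`: the numeric matrix with
#'   `site_id` attribute, dimnames `sample_ids` x `metals`.
#' @examples
#' ct <- concentration_table(cbind(Ni = c(4, 6, 8), Pb = c(10, 12, 14)), "demo")
#' summarize(ct)
#' @export
concentration_table <- function(values, site_id, sample_ids = NULL, metals = NULL) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix or data frame", call. = FALSE)
  }
  if (!is.character(site_id) || length(site_id) != 1L || is.na(site_id)) {
    stop("`site_id` must be a single character label", call. = FALSE)
  }
  if (is.null(metals)) metals <- colnames(values)
  if (is.null(metals)) stop("metal (column) names are required", call. = FALSE)
  if (is.null(sample_ids)) sample_ids <- rownames(values)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (anyDuplicated(metals)) {
    stop("duplicate metal symbols: ",
         paste(unique(metals[duplicated(metals)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "), call. = FALSE)
  }
  if (length(metals) != ncol(values) || length(sample_ids) != nrow(values)) {
    stop("dimnames do not match matrix dimensions", call. = FALSE)
  }
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "concentrations must be finite and >= 0; offending cell: sample '%s', metal '%s' (value %s)",
      sample_ids[bad[1, 1]], metals[bad[1, 2]],
      format(values[bad[1, , drop = FALSE]])), call. = FALSE)
  }
  dimnames(values) <- list(sample_ids, metals)
  structure(values, site_id = site_id, class = c("concentration_table", "matrix", "array"))
}

#' @export
print.concentration_table <- function(x, ...) {
  cat(sprintf("<concentration_table> site '%s': %d samples x %d metals (mg/kg)\n",
              site_id(x), nrow(x), ncol(x)))
  print(utils::head(unclass(x)), ...)
  if (nrow(x) > 6L) cat(sprintf("... %d more samples\n", nrow(x) - 6L))
  invisible(x)
}

#' Site label of a concentration table
#' @param table A [concentration_table()].
#' @return Character scalar.
#' @export
site_id <- function(table) attr(table, "site_id")

#' Metal symbols of a concentration table
#' @param table A [concentration_table()].
#' @return Character vector of column labels.
#' @export
metals <- function(table) colnames(table)

#' Read a per-sample concentration table from CSV
#'
#' The expected layout is tidy CSV, UTF-8, dot decimal: one row per soil
#' sample, one column per metal, values in mg/kg dry weight. An optional
#' leading non-numeric column is taken as sample identifiers.
#'
#' @param path Path to an existing CSV file.
#' @param site_id Character label for the site the samples came from.
#' @return A validated [concentration_table()], with row and column order
#'   preserved from the file.
#' @export
read_concentration_table <- function(path, site_id) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 1L) stop("empty table: ", path, call. = FALSE)
  sample_ids <- NULL
  if (!is.numeric(df[[1]]) && !all(grepl("^\\s*-?[0-9.eE+]+\\s*$", df[[1]]))) {
    sample_ids <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
  }
  for (j in seq_along(df)) {
    col <- df[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      if (anyNA(num) & !anyNA(col)) {
        row <- which(is.na(num))[1]
        stop(sprintf("non-numeric value '%s' in column '%s', row %d of %s",
                     col[row], names(df)[j], row, path), call. = FALSE)
      }
      df[[j]] <- num
    }
    if (anyNA(df[[j]])) {
      stop(sprintf("missing value in column '%s', row %d of %s",
                   names(df)[j], which(is.na(df[[j]]))[1], path), call. = FALSE)
    }
    if (any(df[[j]] < 0)) {
      stop(sprintf("negative concentration for metal '%s' at row %d of %s",
                   names(df)[j], which(df[[j]] < 0)[1], path), call. = FALSE)
    }
  }
  concentration_table(as.matrix(df), site_id = site_id, sample_ids = sample_ids)
}

#' Write a concentration table to CSV
#'
#' Writes full precision so that read -> write -> read round-trips the
#' table exactly. The sample identifiers go in a leading `sample` column.
#'
#' @param table A [concentration_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_concentration_table <- function(table, path) {
  stopifnot(inherits(table, "concentration_table"))
  vals <- apply(unclass(table), c(1, 2), function(v) sprintf("%.17g", v))
  df <- data.frame(sample = rownames(table), vals,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
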