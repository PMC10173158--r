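#' Format a risk quantity in 3-significant-figure scientific notation
#'
#' Risk indices span many orders of magnitude, so reports render them as
#' e.g. `"3.38E-1"` or `"1.62E-3"` (mantissa to two decimals, exponent
#' without padding).
#'
#' @param x Numeric vector.
#' @return Character vector.
#' @examples
#' format_risk(0.337808)  # "3.38E-1"
#' @export
format_risk <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    if (v == 0) return("0.00E0")
    e <- floor(log10(abs(v)))
    m <- v / 10^e
    # guard against mantissa rounding to 10
    if (round(abs(m), 2) >= 10) { m <- m / 10; e <- e + 1 }
    sprintf("%.2fE%d", m, e)
  }, character(1))
}

#' Format a descriptive statistic to two decimals
#' @param x Numeric vector.
#' @return Character vector, e.g. `"6.37"`.
#' @export
format_stat <- function(x) {
  ifelse(is.na(x), NA_character_, sprintf("%.2f", x))
}

#' Write a result object to disk
#'
#' Accepts any of the package's result objects — [summarize()] output,
#' [pearson_matrix()] output, [assess_site()] output or a
#' `simulation_result` — flattens it to a table and writes JSON, CSV or
#' aligned plain text. Risk quantities are rendered in 3-significant-figure
#' scientific notation ([format_risk()]); descriptive statistics to two
#' decimals ([format_stat()]); field order is deterministic.
#'
#' @param results A result object (or a plain data frame).
#' @param path Output file path.
#' @param format `"json"`, `"csv"` or `"text"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("json", "csv", "text")) {
  format <- match.arg(format)
  df <- report_frame(results)
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot write to '", path, "': ", conditionMessage(e), call. = FALSE)
  })
  on.exit(close(con))
  if (format == "json") {
    writeLines(jsonlite::toJSON(df, dataframe = "rows", pretty = TRUE, na = "null"), con)
  } else if (format == "csv") {
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE, na = "")
  } else {
    if (nrow(df) == 0L) {
      writeLines("(empty report)", con)
    } else {
      writeLines(utils::capture.output(print.data.frame(df, row.names = FALSE)), con)
    }
  }
  invisible(path)
}

# flatten any result object to a data frame with pre-formatted columns
report_frame <- function(results) {
  if (is.null(results) || (is.list(results) && length(results) == 0L)) {
    return(data.frame())
  }
  if (inherits(results, "summary_statistics")) {
    df <- as.data.frame(results)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], format_stat)
    return(df)
  }
  if (inherits(results, "correlation_result")) {
    R <- results$R
    R[upper.tri(R)] <- NA
    df <- data.frame(metal = rownames(R), round(R, 4), check.names = FALSE)
    rownames(df) <- NULL
    return(df)
  }
  if (inherits(results, "risk_result")) {
    df <- as.data.frame(results)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], format_risk)
    return(df)
  }
  if (inherits(results, "simulation_result")) {
    df <- results$summary
    num <- vapply(df, is.numeric, logical(1))
    risky <- num & !grepl("^prob_", names(df))
    df[risky] <- lapply(df[risky], format_risk)
    df[num & !risky] <- lapply(df[num & !risky], function(x) sprintf("%.4f", x))
    return(df)
  }
  if (is.data.frame(results)) return(results)
  stop("unsupported result object of class ", paste(class(results), collapse = "/"),
       call. = FALSE)
}
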