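#' Per-metal summary statistics of a concentration table
#'
#' Computes, for every metal column, the spreadsheet-style 13-statistic
#' summary used in environmental geochemistry reports: minimum, maximum,
#' mean, standard error of the mean, median, sample standard deviation
#' (n - 1 denominator), variance, excess kurtosis, skewness, range, sum and
#' count, plus a symmetry label from [classify_symmetry()].
#'
#' Shape statistics follow the sample-size-corrected spreadsheet
#' conventions: adjusted Fisher-Pearson skewness (defined for n >= 3) and
#' excess kurtosis with the KURT bias correction (defined for n >= 4).
#' Below those counts the fields are `NA` and flagged, never silently zero.
#' The even-count median is the mean of the two central order statistics.
#'
#' @param table A [concentration_table()] with at least 2 samples.
#' @return A `summary_statistics` data frame, one row per metal, with the
#'   statistics as columns (concentration-valued columns in mg/kg;
#'   skewness/kurtosis unitless) and the site label as attribute `site_id`.
#' @examples
#' ct <- concentration_table(cbind(Ni = c(1, 2, 3, 4)), "demo")
#' summarize(ct)
#' @export
summarize <- function(table) {
  stopifnot(inherits(table, "concentration_table"))
  n <- nrow(table)
  if (n < 2L) stop("at least 2 samples are required for summary statistics", call. = FALSE)
  one <- function(x) {
    s <- stats::sd(x)
    data.frame(
      min = min(x), max = max(x), mean = mean(x),
      std_error = s / sqrt(n),
      median = stats::median(x),
      sd = s, variance = s^2,
      kurtosis = if (n >= 4L) e1071::kurtosis(x, type = 2) else NA_real_,
      skewness = if (n >= 3L) e1071::skewness(x, type = 2) else NA_real_,
      range = max(x) - min(x), sum = sum(x), count = n
    )
  }
  out <- do.call(rbind, lapply(seq_len(ncol(table)), function(j) one(table[, j])))
  out <- cbind(metal = metals(table), out)
  out$symmetry <- ifelse(is.na(out$skewness), NA_character_,
                         vapply(out$skewness, classify_symmetry, character(1)))
  rownames(out) <- NULL
  structure(out, site_id = site_id(table),
            class = c("summary_statistics", "data.frame"))
}

#' Classify a skewness value as approximately symmetric or skewed
#'
#' Distributions with skewness inside the interval \[-1, 1\] are treated as
#' approximately symmetric, the usual screening rule for deciding whether
#' concentration data need a transformed scale.
#'
#' @param skewness Finite unitless skewness.
#' @return `"approximately symmetric"` if `|skewness| <= 1`, else `"skewed"`.
#' @examples
#' classify_symmetry(0.9)
#' classify_symmetry(1.5)
#' @export
classify_symmetry <- function(skewness) {
  if (!is.numeric(skewness) || length(skewness) != 1L || !is.finite(skewness)) {
    stop("skewness must be a single finite number", call. = FALSE)
  }
  if (abs(skewness) <= 1) "approximately symmetric" else "skewed"
}

#' @export
print.summary_statistics <- function(x, ...) {
  cat(sprintf("<summary_statistics> site '%s' (%d metals, n = %d)\n",
              attr(x, "site_id"), nrow(x), x$count[1]))
  print.data.frame(x, digits = 4, row.names = FALSE, ...)
  invisible(x)
}
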