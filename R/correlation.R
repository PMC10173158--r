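#' Pearson correlation matrix across metals
#'
#' Computes the product-moment correlation between every pair of metal
#' columns and attaches the four-tier magnitude categorization from
#' [categorize_correlation()]. Zero-variance columns produce undefined
#' entries: these are set to `NA`, recorded in the `undefined` matrix and
#' reported with a warning rather than propagating silent `NaN`s.
#'
#' @param table A [concentration_table()] with at least 3 samples.
#' @return A `correlation_result`: list with `metals`, the symmetric matrix
#'   `R` (unit diagonal), the matching `categories` character matrix and a
#'   logical `undefined` matrix flagging entries involving constant columns.
#' @examples
#' ct <- concentration_table(cbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4)), "demo")
#' pearson_matrix(ct)$R
#' @export
pearson_matrix <- function(table) {
  stopifnot(inherits(table, "concentration_table"))
  if (nrow(table) < 3L) stop("at least 3 samples are required for correlation", call. = FALSE)
  x <- unclass(table)
  sds <- apply(x, 2, stats::sd)
  constant <- sds == 0
  R <- suppressWarnings(stats::cor(x, method = "pearson"))
  undefined <- outer(constant, constant, `|`)
  diag(undefined) <- FALSE
  R[undefined] <- NA_real_
  diag(R) <- 1
  if (any(constant)) {
    warning("zero-variance column(s), correlations undefined: ",
            paste(colnames(x)[constant], collapse = ", "), call. = FALSE)
  }
  categories <- matrix(NA_character_, ncol(x), ncol(x),
                       dimnames = dimnames(R))
  ok <- !is.na(R)
  categories[ok] <- categorize_correlation(R[ok])
  diag(categories) <- NA_character_
  structure(list(metals = colnames(x), R = R, categories = categories,
                 undefined = undefined, site_id = site_id(table)),
            class = "correlation_result")
}

#' Four-tier categorization of a Pearson coefficient
#'
#' Magnitude tiers conventional in trace-element geochemistry:
#' `|R| >= 0.8` strong, `0.5 <= |R| < 0.8` significant, `0.3 <= |R| < 0.5`
#' weak, `|R| < 0.3` insignificant. Published tier bounds overlap at 0.5 and
#' 0.8; boundaries are assigned to the stronger tier, the conservative choice
#' for flagging association.
#'
#' @param r Numeric vector of correlation coefficients, each in \[-1, 1\].
#' @return Character vector of labels.
#' @examples
#' categorize_correlation(c(0.3431, -0.0554, 0.8))
#' @export
categorize_correlation <- function(r) {
  if (!is.numeric(r) || any(!is.finite(r)) || any(abs(r) > 1 + 1e-12)) {
    stop("correlation coefficients must be finite and within [-1, 1]", call. = FALSE)
  }
  a <- abs(r)
  ifelse(a >= 0.8, "strong",
         ifelse(a >= 0.5, "significant",
                ifelse(a >= 0.3, "weak", "insignificant")))
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> site '%s' (%d metals)\n", x$site_id, length(x$metals)))
  R <- x$R
  R[upper.tri(R)] <- NA  # lower-triangle reporting order
  print(round(R, 4), na.print = "", ...)
  invisible(x)
}
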