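#' Distribution specification for an uncertain model input
#'
#' @param name Symbol the risk model reads: `"IngRs"`, `"BW"`,
#'   `"Cs_<metal>"` or `"SF_<metal>"`.
#' @param family One of `"point"`, `"normal"`, `"lognormal"`, `"uniform"`,
#'   `"triangular"`.
#' @param ... Family parameters: `value` (point); `mean`, `sd` (normal);
#'   `meanlog`, `sdlog` (lognormal); `min`, `max` (uniform); `min`, `mode`,
#'   `max` (triangular).
#' @param truncation Optional `c(lower, upper)` bounds applied by inverse-CDF
#'   conditioning (families other than point).
#' @return A `distribution_spec` object.
#' @examples
#' dist_spec("BW", "normal", mean = 70, sd = 14, truncation = c(40, 120))
#' @export
dist_spec <- function(name, family = c("point", "normal", "lognormal", "uniform", "triangular"),
                      ..., truncation = NULL) {
  family <- match.arg(family)
  pars <- list(...)
  need <- switch(family,
    point = "value", normal = c("mean", "sd"), lognormal = c("meanlog", "sdlog"),
    uniform = c("min", "max"), triangular = c("min", "mode", "max"))
  missing <- setdiff(need, names(pars))
  if (length(missing) > 0L) {
    stop(sprintf("%s distribution for '%s' needs parameter(s): %s",
                 family, name, paste(missing, collapse = ", ")), call. = FALSE)
  }
  extra <- setdiff(names(pars), need)
  if (length(extra) > 0L) {
    stop("unknown parameter(s) for ", family, ": ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  for (nm in need) {
    if (!is.numeric(pars[[nm]]) || length(pars[[nm]]) != 1L || !is.finite(pars[[nm]])) {
      stop(sprintf("parameter '%s' for '%s' must be a single finite number", nm, name),
           call. = FALSE)
    }
  }
  if (family %in% c("normal", "lognormal") && pars[[need[2]]] < 0) {
    stop("sd must be >= 0 for '", name, "'", call. = FALSE)
  }
  if (family == "uniform" && pars$min >= pars$max) {
    stop("uniform needs min < max for '", name, "'", call. = FALSE)
  }
  if (family == "triangular" && !(pars$min <= pars$mode && pars$mode <= pars$max && pars$min < pars$max)) {
    stop("triangular needs min <= mode <= max and min < max for '", name, "'", call. = FALSE)
  }
  if (!is.null(truncation)) {
    if (family == "point") stop("truncation does not apply to a point mass", call. = FALSE)
    if (length(truncation) != 2L || !all(is.finite(truncation)) || truncation[1] >= truncation[2]) {
      stop("truncation must be c(lower, upper) with lower < upper", call. = FALSE)
    }
  }
  structure(list(name = name, family = family, pars = pars, truncation = truncation),
            class = "distribution_spec")
}

#' @export
print.distribution_spec <- function(x, ...) {
  cat(sprintf("<distribution_spec> %s ~ %s(%s)%s\n", x$name, x$family,
              paste(sprintf("%s=%g", names(x$pars), unlist(x$pars)), collapse = ", "),
              if (is.null(x$truncation)) "" else
                sprintf(" truncated to [%g, %g]", x$truncation[1], x$truncation[2])))
  invisible(x)
}

#' Seeded draws from a distribution spec
#'
#' Sampling is by inverse CDF: uniforms are drawn on the truncated
#' probability range and pushed through the family quantile function, so
#' truncation is exact and `(spec, n, seed)` fully determines the output.
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws, >= 1.
#' @param seed Integer seed.
#' @return Numeric vector of length `n`.
#' @export
sample_dist <- function(spec, n, seed) {
  stopifnot(inherits(spec, "distribution_spec"), n >= 1)
  check_seed(seed)
  withr::with_seed(as.integer(seed), {
    u <- stats::runif(n)
  })
  quantile_dist(spec, u)
}

quantile_dist <- function(spec, u) {
  p <- spec$pars
  qf <- switch(spec$family,
    point = function(q) rep(p$value, length(q)),
    normal = function(q) stats::qnorm(q, p$mean, p$sd),
    lognormal = function(q) stats::qlnorm(q, p$meanlog, p$sdlog),
    uniform = function(q) stats::qunif(q, p$min, p$max),
    triangular = function(q) qtri(q, p$min, p$mode, p$max))
  if (!is.null(spec$truncation)) {
    cdf <- switch(spec$family,
      normal = function(x) stats::pnorm(x, p$mean, p$sd),
      lognormal = function(x) stats::plnorm(x, p$meanlog, p$sdlog),
      uniform = function(x) stats::punif(x, p$min, p$max),
      triangular = function(x) ptri(x, p$min, p$mode, p$max))
    lo <- cdf(spec$truncation[1]); hi <- cdf(spec$truncation[2])
    if (hi <= lo) stop("truncation interval has zero probability for '", spec$name, "'",
                       call. = FALSE)
    u <- lo + u * (hi - lo)
  }
  qf(u)
}

# triangular CDF / quantile (closed forms)
ptri <- function(x, a, c, b) {
  out <- numeric(length(x))
  out[x >= b] <- 1
  i <- x > a & x < c
  out[i] <- (x[i] - a)^2 / ((b - a) * (c - a))
  j <- x >= c & x < b
  out[j] <- 1 - (b - x[j])^2 / ((b - a) * (b - c))
  out
}

qtri <- function(u, a, c, b) {
  f <- (c - a) / (b - a)
  ifelse(u < f, a + sqrt(u * (b - a) * (c - a)),
         b - sqrt((1 - u) * (b - a) * (b - c)))
}

#' Default uncertain-input distributions for the cancer-risk simulation
#'
#' The uncertain inputs of the ingestion cancer-risk model are the soil
#' concentration of each carcinogen, the soil ingestion rate, the body
#' weight and the slope factor. Defaults: each concentration is lognormal
#' with moments matched to the site's sample mean and SD, truncated to the
#' sample range (a constant column degrades to a point mass with a warning);
#' body weight is normal(70 kg, CV 0.2) truncated to \[40, 120\] kg; the
#' ingestion rate is triangular(50, 100, 200) mg/day; each slope factor is a
#' point mass at its configured value. All are ordinary [dist_spec()]
#' objects, so any can be replaced before [run_simulation()].
#'
#' @param table A [concentration_table()].
#' @param p [load_exposure_parameters()] output (supplies the BW and IngRs
#'   central values).
#' @param tox [load_toxicity_profiles()] output.
#' @param metals Metals to include; defaults to the carcinogens present in
#'   both `table` and `tox`.
#' @return Named list of [dist_spec()] objects.
#' @export
build_default_distributions <- function(table, p = load_exposure_parameters(),
                                        tox = load_toxicity_profiles(),
                                        metals = NULL) {
  stopifnot(inherits(table, "concentration_table"))
  if (is.null(metals)) {
    metals <- Filter(function(m) !is.null(tox[[m]]) && tox[[m]]$carcinogen,
                     colnames(table))
  }
  if (length(metals) == 0L) stop("no carcinogenic metal present in the table", call. = FALSE)
  specs <- list(
    IngRs = dist_spec("IngRs", "triangular", min = p$IngRs / 2, mode = p$IngRs,
                      max = p$IngRs * 2),
    BW = dist_spec("BW", "normal", mean = p$BW, sd = 0.2 * p$BW, truncation = c(40, 120))
  )
  for (m in metals) {
    x <- table[, m]
    nm <- paste0("Cs_", m)
    if (stats::sd(x) == 0) {
      warning("zero variance for '", m, "': concentration treated as a point mass",
              call. = FALSE)
      specs[[nm]] <- dist_spec(nm, "point", value = mean(x))
    } else {
      s2 <- log(1 + (stats::sd(x) / mean(x))^2)
      specs[[nm]] <- dist_spec(nm, "lognormal", meanlog = log(mean(x)) - s2 / 2,
                               sdlog = sqrt(s2), truncation = range(x))
    }
    specs[[paste0("SF_", m)]] <- dist_spec(paste0("SF_", m), "point",
                                           value = tox[[m]]$SF_ing)
  }
  specs
}

#' Monte Carlo propagation of uncertainty through the cancer-risk model
#'
#' Per iteration, every uncertain input is drawn independently from its
#' [dist_spec()] and the ingestion-route incremental lifetime cancer risk is
#' evaluated per metal and summed:
#' `ILCR_m = Cs_m x IngRs x EF x ED x CF / (BW x AT_ca) x SF_m`.
#' Exposure constants not covered by a spec (`EF`, `ED`, `CF`, `AT_ca`)
#' stay fixed at their [load_exposure_parameters()] values. With
#' `include_hi = TRUE` the non-carcinogenic hazard index over all three
#' pathways is propagated as well, using the same draws.
#'
#' @param table A [concentration_table()] (defines which metals are modelled
#'   and, through [build_default_distributions()], the default concentration
#'   distributions).
#' @param p,tox Exposure parameters and toxicity profiles.
#' @param specs Named list of [dist_spec()] objects; defaults to
#'   [build_default_distributions()]. A `Cs_<metal>` or `SF_<metal>` spec
#'   must exist for every simulated carcinogen — a missing symbol is an
#'   error before any sampling.
#' @param n_iterations Number of Monte Carlo iterations (default 10000).
#' @param seed Integer seed; identical inputs give a bit-identical result.
#' @param include_hi Also propagate the hazard index.
#' @return A `simulation_result`: list with `n_iterations`, `seed`, `draws`
#'   (matrix of per-iteration ILCR per metal, total ILCR and optionally HI),
#'   and the [summarize_simulation()] table in `$summary`.
#' @examples
#' ct <- concentration_table(cbind(As = c(18, 22, 26, 30)), "demo")
#' res <- run_simulation(ct, n_iterations = 500, seed = 7)
#' res$summary
#' @export
run_simulation <- function(table, p = load_exposure_parameters(),
                           tox = load_toxicity_profiles(), specs = NULL,
                           n_iterations = 10000, seed = 1, include_hi = FALSE) {
  stopifnot(inherits(table, "concentration_table"), n_iterations >= 1)
  check_seed(seed)
  mets <- Filter(function(m) !is.null(tox[[m]]) && tox[[m]]$carcinogen, colnames(table))
  if (length(mets) == 0L) stop("no carcinogenic metal present in the table", call. = FALSE)
  if (is.null(specs)) specs <- build_default_distributions(table, p, tox, metals = mets)
  required <- c("IngRs", "BW", paste0("Cs_", mets), paste0("SF_", mets))
  fixed <- list(IngRs = p$IngRs, BW = p$BW)
  for (sym in required) {
    if (is.null(specs[[sym]])) {
      if (sym %in% names(fixed)) {
        specs[[sym]] <- dist_spec(sym, "point", value = fixed[[sym]])
      } else {
        stop("no distribution spec for model symbol '", sym, "'", call. = FALSE)
      }
    }
  }

  n <- as.integer(n_iterations)
  withr::with_seed(as.integer(seed), {
    u <- matrix(stats::runif(n * length(required)), n,
                dimnames = list(NULL, required))
  })
  draw <- function(sym) quantile_dist(specs[[sym]], u[, sym])
  IngRs <- draw("IngRs"); BW <- draw("BW")
  base_ca <- IngRs * p$EF * p$ED * p$CF / (BW * p$AT_ca)
  out <- matrix(0, n, length(mets) + 1L,
                dimnames = list(NULL, c(paste0("ILCR_", mets), "ILCR_total")))
  for (m in mets) {
    out[, paste0("ILCR_", m)] <- draw(paste0("Cs_", m)) * base_ca * draw(paste0("SF_", m))
  }
  out[, "ILCR_total"] <- rowSums(out[, paste0("ILCR_", mets), drop = FALSE])

  if (include_hi) {
    base_nc <- IngRs * p$EF * p$ED * p$CF / (BW * p$AT_nc)
    hi <- numeric(n)
    for (m in colnames(table)) {
      prof <- tox[[m]]
      if (is.null(prof)) next
      sym <- paste0("Cs_", m)
      cs <- if (sym %in% colnames(u)) draw(sym) else mean(table[, m])
      if (!is.null(prof$RfD_ing)) hi <- hi + cs * base_nc / prof$RfD_ing
      if (!is.null(prof$RfD_inh)) {
        hi <- hi + cs * p$InhRs * p$EF * p$ED / (p$PEF * BW * p$AT_nc) / prof$RfD_inh
      }
      if (!is.null(prof$RfD_derm)) {
        hi <- hi + cs * p$SA * p$AF * abs_fraction(p, m) * p$EF * p$ED * p$CF /
          (BW * p$AT_nc) / prof$RfD_derm
      }
    }
    out <- cbind(out, HI = hi)
  }

  res <- structure(list(site_id = site_id(table), n_iterations = n, seed = as.integer(seed),
                        draws = out), class = "simulation_result")
  res$summary <- summarize_simulation(res)
  res
}

#' Percentile and exceedance summary of a simulation
#'
#' Empirical quantiles use the default linear-interpolation convention
#' (`stats::quantile(type = 7)`), documented here for bit-reproducibility.
#' Each percentile of a risk output is labelled against the cancer-risk
#' acceptability band: below 1e-6 negligible, 1e-6 to 1e-4 acceptable
#' (boundaries inclusive), above 1e-4 high.
#'
#' @param result A `simulation_result` (or any list with a `draws` matrix).
#' @param percentiles Percentile points in (0, 100); default 5, 50, 95.
#' @return Data frame, one row per output, with mean, the requested
#'   percentiles, band labels per percentile, and exceedance probabilities
#'   of the 1e-6 and 1e-4 thresholds.
#' @examples
#' summarize_simulation(list(draws = cbind(ILCR_total = (1:100) * 1e-6)))
#' @export
summarize_simulation <- function(result, percentiles = c(5, 50, 95)) {
  draws <- result$draws
  if (is.null(draws) || nrow(draws) == 0L) stop("no draws to summarize", call. = FALSE)
  if (any(percentiles <= 0 | percentiles >= 100)) {
    stop("percentiles must lie strictly between 0 and 100", call. = FALSE)
  }
  percentiles <- sort(percentiles)
  rows <- lapply(colnames(draws), function(nm) {
    x <- draws[, nm]
    q <- stats::quantile(x, percentiles / 100, type = 7, names = FALSE)
    row <- data.frame(output = nm, mean = mean(x), stringsAsFactors = FALSE)
    for (i in seq_along(percentiles)) {
      row[[sprintf("p%g", percentiles[i])]] <- q[i]
    }
    if (nm != "HI") {
      for (i in seq_along(percentiles)) {
        row[[sprintf("band_p%g", percentiles[i])]] <- classify_risk(0, q[i])$cancer
      }
      row$prob_gt_1e6 <- mean(x > 1e-6)
      row$prob_gt_1e4 <- mean(x > 1e-4)
    }
    row
  })
  out <- do.call(rbind, lapply(rows, function(r) {
    # align columns across outputs (HI rows lack band/exceedance fields)
    all_cols <- unique(unlist(lapply(rows, names)))
    for (c in setdiff(all_cols, names(r))) r[[c]] <- NA
    r[all_cols]
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> site '%s': %d iterations, seed %d\n",
              x$site_id, x$n_iterations, x$seed))
  print(x$summary, digits = 3, row.names = FALSE)
  invisible(x)
}
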