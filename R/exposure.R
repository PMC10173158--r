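#' Adult-resident exposure parameters
#'
#' Builds the parameter set entering the chronic-daily-intake equations
#' ([cdi_ingestion()], [cdi_inhalation()], [cdi_dermal()]). Unspecified
#' fields take USEPA RAGS-style adult residential screening defaults; every
#' field can be overridden from a list or a YAML/JSON file.
#'
#' Defaults: soil ingestion rate `IngRs` = 100 mg/day, inhalation rate
#' `InhRs` = 20 m3/day, exposure frequency `EF` = 350 days/yr, exposure
#' duration `ED` = 30 yr, body weight `BW` = 70 kg, non-carcinogenic
#' averaging time `AT_nc` = ED x 365 days, carcinogenic averaging time
#' `AT_ca` = 70 x 365 days (lifetime), particle emission factor
#' `PEF` = 1.36e9 m3/kg, skin area `SA` = 5700 cm2, adherence factor
#' `AF` = 0.07 mg/(cm2 day), dermal absorption fraction `ABS` = 0.001
#' (0.03 for As via `ABS_overrides`), and mass conversion factor
#' `CF` = 1e-6 kg/mg. Risk magnitudes scale directly with these choices,
#' so reported intakes are only as site-specific as the parameter set.
#'
#' @param config Named list of overrides, or path to a YAML/JSON file
#'   containing one. `ABS_overrides` may be a named list/vector of
#'   per-metal dermal absorption fractions.
#' @return An object of class `exposure_parameters` (named list).
#' @examples
#' load_exposure_parameters()
#' load_exposure_parameters(list(EF = 350, ED = 30))
#' @export
load_exposure_parameters <- function(config = list()) {
  config <- read_config(config)
  p <- list(
    IngRs = 100,       # mg/day
    InhRs = 20,        # m3/day
    EF    = 350,       # days/year
    ED    = 30,        # years
    BW    = 70,        # kg
    AT_nc = NA_real_,  # days; defaults to ED * 365 below
    AT_ca = 70 * 365,  # days (lifetime)
    PEF   = 1.36e9,    # m3/kg
    SA    = 5700,      # cm2
    AF    = 0.07,      # mg/(cm2 day)
    ABS   = 0.001,     # unitless default dermal absorption
    CF    = 1e-6       # kg/mg
  )
  abs_overrides <- c(As = 0.03)
  if (!is.null(config$ABS_overrides)) {
    ov <- unlist(config$ABS_overrides)
    abs_overrides[names(ov)] <- ov
    config$ABS_overrides <- NULL
  }
  extra <- setdiff(names(config), names(p))
  if (length(extra) > 0L) {
    stop("unknown exposure parameter(s): ", paste(extra, collapse = ", "), call. = FALSE)
  }
  for (nm in names(config)) {
    v <- config[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("exposure parameter '%s' must be a single finite number", nm),
           call. = FALSE)
    }
    p[[nm]] <- as.numeric(v)
  }
  if (is.na(p$AT_nc)) p$AT_nc <- p$ED * 365
  p$ABS_overrides <- abs_overrides
  validate_exposure_parameters(p)
}

validate_exposure_parameters <- function(p) {
  num <- setdiff(names(p), "ABS_overrides")
  for (nm in num) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0) {
      stop(sprintf("exposure parameter '%s' must be strictly positive (got %s)",
                   nm, format(p[[nm]])), call. = FALSE)
    }
  }
  if (p$EF > 366) stop("EF must be <= 366 days/year", call. = FALSE)
  if (p$ABS > 1) stop("ABS must lie in (0, 1]", call. = FALSE)
  if (any(p$ABS_overrides <= 0 | p$ABS_overrides > 1)) {
    stop("per-metal ABS overrides must lie in (0, 1]", call. = FALSE)
  }
  if (p$AT_nc < p$ED * 365 - 1e-9 || p$AT_ca < p$ED * 365 - 1e-9) {
    stop("averaging times must be >= ED * 365 days", call. = FALSE)
  }
  structure(p, class = "exposure_parameters")
}

#' @export
print.exposure_parameters <- function(x, ...) {
  cat("<exposure_parameters>\n")
  for (nm in setdiff(names(x), "ABS_overrides")) {
    cat(sprintf("  %-6s %g\n", nm, x[[nm]]))
  }
  if (length(x$ABS_overrides) > 0L) {
    cat("  ABS overrides:",
        paste(sprintf("%s=%g", names(x$ABS_overrides), x$ABS_overrides), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Dermal absorption fraction for a metal
#' @param p An `exposure_parameters` object.
#' @param metal Element symbol.
#' @return The per-metal override if present, else the default `ABS`.
#' @export
abs_fraction <- function(p, metal) {
  stopifnot(inherits(p, "exposure_parameters"))
  if (metal %in% names(p$ABS_overrides)) unname(p$ABS_overrides[[metal]]) else p$ABS
}

#' Serialize exposure parameters to a plain list
#'
#' The output of `as.list()` on the result feeds back into
#' [load_exposure_parameters()] unchanged (idempotent load).
#' @param x An `exposure_parameters` object.
#' @param ... Unused.
#' @return A named list suitable for YAML/JSON serialization.
#' @export
as.list.exposure_parameters <- function(x, ...) {
  out <- unclass(x)
  out$ABS_overrides <- as.list(out$ABS_overrides)
  out
}

#' Load per-metal toxicity profiles (reference doses, slope factors)
#'
#' Merges user overrides over the screening-level defaults shipped in
#' `inst/extdata/toxicity_defaults.yaml` (USEPA IRIS-style oral, inhalation
#' and dermal reference doses in mg/(kg day) and oral carcinogenic slope
#' factors in (mg/(kg day))^-1). Metals lacking a reference dose (Mg) or a
#' slope factor are kept and flagged, not rejected: downstream risk code
#' skips them with a warning.
#'
#' @param config Named list of per-metal overrides (each a list with any of
#'   `RfD_ing`, `RfD_inh`, `RfD_derm`, `SF_ing`, `carcinogen`), or a path to
#'   a YAML/JSON file of the same shape. Metals absent from the defaults are
#'   added.
#' @return Named list of `toxicity_profile` objects, one per metal.
#' @examples
#' tox <- load_toxicity_profiles()
#' tox$As
#' @export
load_toxicity_profiles <- function(config = list()) {
  config <- read_config(config)
  defaults <- yaml::read_yaml(system.file("extdata", "toxicity_defaults.yaml",
                                          package = "soilrisk", mustWork = TRUE))
  for (metal in names(config)) {
    ov <- config[[metal]]
    if (!is.list(ov)) stop("override for '", metal, "' must be a named list", call. = FALSE)
    if (is.null(defaults[[metal]])) defaults[[metal]] <- list()
    defaults[[metal]][names(ov)] <- ov
  }
  profiles <- lapply(names(defaults), function(metal) {
    d <- defaults[[metal]]
    toxicity_profile(
      metal      = metal,
      RfD_ing    = d$RfD_ing,
      RfD_inh    = d$RfD_inh,
      RfD_derm   = d$RfD_derm,
      SF_ing     = d$SF_ing,
      carcinogen = isTRUE(d$carcinogen) || (is.null(d$carcinogen) && !is.null(d$SF_ing))
    )
  })
  stats::setNames(profiles, names(defaults))
}

#' Toxicity profile for one metal
#'
#' @param metal Element symbol.
#' @param RfD_ing,RfD_inh,RfD_derm Pathway reference doses, mg/(kg day);
#'   `NULL` when no value is established.
#' @param SF_ing Oral carcinogenic slope factor, (mg/(kg day))^-1, or `NULL`.
#' @param carcinogen Whether the metal enters the cancer-risk total; requires
#'   `SF_ing`.
#' @return A `toxicity_profile` object.
#' @export
toxicity_profile <- function(metal, RfD_ing = NULL, RfD_inh = NULL,
                             RfD_derm = NULL, SF_ing = NULL, carcinogen = !is.null(SF_ing)) {
  for (nm in c("RfD_ing", "RfD_inh", "RfD_derm", "SF_ing")) {
    v <- get(nm)
    if (!is.null(v) && (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)) {
      stop(sprintf("%s for '%s' must be a single strictly positive number", nm, metal),
           call. = FALSE)
    }
  }
  if (isTRUE(carcinogen) && is.null(SF_ing)) {
    stop("carcinogen flag for '", metal, "' requires SF_ing", call. = FALSE)
  }
  structure(list(metal = metal, RfD_ing = RfD_ing, RfD_inh = RfD_inh,
                 RfD_derm = RfD_derm, SF_ing = SF_ing, carcinogen = isTRUE(carcinogen)),
            class = "toxicity_profile")
}

#' @export
print.toxicity_profile <- function(x, ...) {
  fmt <- function(v) if (is.null(v)) "-" else format(v)
  cat(sprintf("<toxicity_profile> %s: RfD ing %s / inh %s / derm %s; SF_ing %s%s\n",
              x$metal, fmt(x$RfD_ing), fmt(x$RfD_inh), fmt(x$RfD_derm), fmt(x$SF_ing),
              if (x$carcinogen) " (carcinogen)" else ""))
  invisible(x)
}

# Accept an in-memory list or a YAML/JSON file path.
read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    if (grepl("\\.json$", config, ignore.case = TRUE)) {
      return(jsonlite::read_json(config, simplifyVector = TRUE))
    }
    return(yaml::read_yaml(config))
  }
  if (is.null(config)) return(list())
  if (!is.list(config)) stop("config must be a named list or a file path", call. = FALSE)
  config
}
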