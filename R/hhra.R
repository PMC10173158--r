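#' Chronic daily intake via incidental soil ingestion
#'
#' CDI_ing = Cs x IngRs x EF x ED x CF / (BW x AT), in mg/(kg day). `CF`
#' (kg/mg) converts the soil concentration from mg/kg to kg-consistent mass
#' units; without it the intake would be off by a factor of 1e6. `AT` is the
#' non-carcinogenic averaging time (`AT_nc`, exposure period) or the
#' carcinogenic one (`AT_ca`, lifetime) depending on `averaging`.
#'
#' @param Cs Soil concentration(s), mg/kg; vectorized.
#' @param p [load_exposure_parameters()] output.
#' @param averaging `"nc"` (default) or `"ca"`.
#' @return Intake in mg/(kg day), same length as `Cs`.
#' @examples
#' p <- load_exposure_parameters()
#' cdi_ingestion(23.17, p)            # ~3.17e-5
#' @export
cdi_ingestion <- function(Cs, p, averaging = c("nc", "ca")) {
  check_cs(Cs)
  AT <- pick_at(p, averaging)
  Cs * p$IngRs * p$EF * p$ED * p$CF / (p$BW * AT)
}

#' Chronic daily intake via inhalation of resuspended soil particles
#'
#' CDI_inh = Cs x InhRs x EF x ED / (PEF x BW x AT), in mg/(kg day). The
#' particle emission factor PEF (m3/kg) converts the soil concentration to an
#' inhalable dust concentration, so no separate mass conversion is needed.
#'
#' @inheritParams cdi_ingestion
#' @return Intake in mg/(kg day).
#' @export
cdi_inhalation <- function(Cs, p, averaging = c("nc", "ca")) {
  check_cs(Cs)
  AT <- pick_at(p, averaging)
  Cs * p$InhRs * p$EF * p$ED / (p$PEF * p$BW * AT)
}

#' Chronic daily intake via dermal contact with soil
#'
#' CDI_derm = Cs x SA x AF x ABS x EF x ED x CF / (BW x AT), in mg/(kg day),
#' with the dermal absorption fraction ABS resolved per metal
#' (see [abs_fraction()]).
#'
#' @inheritParams cdi_ingestion
#' @param metal Element symbol, used to look up a per-metal ABS override.
#' @return Intake in mg/(kg day).
#' @export
cdi_dermal <- function(Cs, p, metal, averaging = c("nc", "ca")) {
  check_cs(Cs)
  AT <- pick_at(p, averaging)
  Cs * p$SA * p$AF * abs_fraction(p, metal) * p$EF * p$ED * p$CF / (p$BW * AT)
}

#' Non-carcinogenic hazard quotient
#'
#' HQ = CDI / RfD. Values above 1 indicate an increased probability of
#' adverse non-cancer effects.
#'
#' @param cdi Chronic daily intake, mg/(kg day).
#' @param rfd Reference dose, mg/(kg day); must be strictly positive.
#' @return Unitless quotient.
#' @export
hazard_quotient <- function(cdi, rfd) {
  if (!is.numeric(rfd) || any(!is.finite(rfd)) || any(rfd <= 0)) {
    stop("RfD must be strictly positive", call. = FALSE)
  }
  if (any(cdi < 0)) stop("CDI must be >= 0", call. = FALSE)
  cdi / rfd
}

#' Hazard index: sum of hazard quotients
#'
#' HI = sum(HQ), typically over the three exposure pathways (or over metals
#' within a pathway). HI < 1 is the USEPA acceptability criterion.
#'
#' @param hq Numeric vector of non-negative hazard quotients.
#' @return Unitless sum.
#' @examples
#' hazard_index(c(2.93e-1, 9.08e-4, 4.39e-2))  # 0.338 at 3 s.f.
#' @export
hazard_index <- function(hq) {
  if (any(!is.finite(hq)) || any(hq < 0)) stop("hazard quotients must be finite and >= 0", call. = FALSE)
  sum(hq)
}

#' Incremental lifetime cancer risk
#'
#' ILCR = CDI x SF, with CDI averaged over a lifetime (`AT_ca`) and SF the
#' oral carcinogenic slope factor in (mg/(kg day))^-1.
#'
#' @param cdi_ca Lifetime-averaged chronic daily intake, mg/(kg day).
#' @param sf Slope factor, >= 0.
#' @return Unitless excess cancer risk.
#' @export
ilcr <- function(cdi_ca, sf) {
  if (!is.numeric(sf) || any(!is.finite(sf)) || any(sf < 0)) {
    stop("slope factor must be finite and >= 0", call. = FALSE)
  }
  if (any(cdi_ca < 0)) stop("CDI must be >= 0", call. = FALSE)
  cdi_ca * sf
}

#' Classify risk indices against regulatory thresholds
#'
#' Non-cancer: HI < 1 is `"acceptable"`, otherwise `"elevated"`. Cancer:
#' ILCR below 1e-6 is `"negligible"`, within \[1e-6, 1e-4\] `"acceptable"`
#' (boundaries inclusive), above 1e-4 `"high"`.
#'
#' @param hi Hazard index, finite and >= 0.
#' @param ilcr Total incremental lifetime cancer risk, finite and >= 0.
#' @return List with `noncancer` and `cancer` labels.
#' @examples
#' classify_risk(0.338, 2.63e-3)
#' @export
classify_risk <- function(hi, ilcr) {
  if (!is.finite(hi) || hi < 0 || !is.finite(ilcr) || ilcr < 0) {
    stop("hi and ilcr must be finite and >= 0", call. = FALSE)
  }
  list(
    noncancer = if (hi < 1) "acceptable" else "elevated",
    cancer = if (ilcr < 1e-6) "negligible" else if (ilcr <= 1e-4) "acceptable" else "high"
  )
}

#' Deterministic site-level risk assessment
#'
#' Runs the full deterministic pipeline on one site: per-metal mean
#' concentrations as the exposure point concentration, chronic daily intakes
#' by ingestion, inhalation and dermal contact (both averaging modes),
#' hazard quotients per metal and pathway where a reference dose exists,
#' pathway target hazard quotients (THQ, the metal sum), their sum the
#' hazard index, and ingestion-route incremental lifetime cancer risk for
#' the flagged carcinogens.
#'
#' Metals lacking a reference dose on some pathway (e.g. Mg) or a slope
#' factor are skipped with a warning, never silently scored zero.
#'
#' @param table A [concentration_table()].
#' @param p [load_exposure_parameters()] output; defaults used if omitted.
#' @param tox [load_toxicity_profiles()] output; defaults used if omitted.
#' @param pathways Character subset of `c("ingestion", "inhalation", "dermal")`.
#' @return A `risk_result`: list with the exposure point concentrations `cs`,
#'   per metal x pathway `cdi_nc`/`cdi_ca` matrices, `hq` matrix, `thq`
#'   (named pathway sums), `hi`, `ilcr_by_metal`, `ilcr_total`,
#'   `classification` and the skip `warnings`.
#' @examples
#' ct <- concentration_table(cbind(As = c(20, 26), Pb = c(400, 500)), "demo")
#' res <- assess_site(ct)
#' res$hi
#' @export
assess_site <- function(table, p = load_exposure_parameters(),
                        tox = load_toxicity_profiles(),
                        pathways = c("ingestion", "inhalation", "dermal")) {
  stopifnot(inherits(table, "concentration_table"))
  pathways <- match.arg(pathways, several.ok = TRUE)
  mets <- metals(table)
  cs <- colMeans(table)

  cdi_fun <- list(
    ingestion  = function(m, avg) cdi_ingestion(cs[[m]], p, avg),
    inhalation = function(m, avg) cdi_inhalation(cs[[m]], p, avg),
    dermal     = function(m, avg) cdi_dermal(cs[[m]], p, m, avg)
  )
  rfd_field <- c(ingestion = "RfD_ing", inhalation = "RfD_inh", dermal = "RfD_derm")

  cdi_nc <- cdi_ca <- hq <- matrix(
    NA_real_, length(mets), length(pathways), dimnames = list(mets, pathways))
  notes <- character()
  for (m in mets) {
    prof <- tox[[m]]
    if (is.null(prof)) {
      notes <- c(notes, sprintf("metal '%s' has no toxicity profile; excluded from HQ and ILCR", m))
    }
    for (pw in pathways) {
      cdi_nc[m, pw] <- cdi_fun[[pw]](m, "nc")
      cdi_ca[m, pw] <- cdi_fun[[pw]](m, "ca")
      rfd <- if (is.null(prof)) NULL else prof[[rfd_field[[pw]]]]
      if (is.null(rfd)) {
        if (!is.null(prof)) {
          notes <- c(notes, sprintf("no %s RfD for '%s'; skipped in %s HQ", pw, m, pw))
        }
      } else {
        hq[m, pw] <- hazard_quotient(cdi_nc[m, pw], rfd)
      }
    }
  }
  if (all(is.na(hq))) stop("no metal has a reference dose: hazard index undefined", call. = FALSE)
  thq <- colSums(hq, na.rm = TRUE)
  hi <- hazard_index(thq)

  ilcr_by_metal <- stats::setNames(numeric(0), character(0))
  if ("ingestion" %in% pathways) {
    for (m in mets) {
      prof <- tox[[m]]
      if (!is.null(prof) && prof$carcinogen) {
        ilcr_by_metal[[m]] <- ilcr(cdi_ca[m, "ingestion"], prof$SF_ing)
      } else if (!is.null(prof) && is.null(prof$SF_ing)) {
        notes <- c(notes, sprintf("no slope factor for '%s'; excluded from ILCR", m))
      }
    }
  }
  ilcr_total <- sum(ilcr_by_metal)
  for (w in unique(notes)) warning(w, call. = FALSE)

  structure(list(
    site_id = site_id(table), pathways = pathways, cs = cs,
    cdi_nc = cdi_nc, cdi_ca = cdi_ca, hq = hq, thq = thq, hi = hi,
    ilcr_by_metal = ilcr_by_metal, ilcr_total = ilcr_total,
    classification = classify_risk(hi, ilcr_total),
    warnings = unique(notes)
  ), class = "risk_result")
}

#' Flatten a risk result to a one-row report table
#'
#' Columns mirror the conventional site-summary layout: metal-summed mean
#' CDI per pathway (non-carcinogenic averaging), THQ per pathway, HI and
#' total ILCR.
#'
#' @param x A `risk_result`.
#' @param ... Unused.
#' @return One-row data frame.
#' @export
as.data.frame.risk_result <- function(x, ...) {
  pw <- c(ingestion = "ing", inhalation = "inh", dermal = "derm")
  out <- data.frame(site = x$site_id, stringsAsFactors = FALSE)
  for (p in x$pathways) out[[paste0("CDI_", pw[[p]])]] <- sum(x$cdi_nc[, p])
  for (p in x$pathways) out[[paste0("THQ_", pw[[p]])]] <- x$thq[[p]]
  out$HI <- x$hi
  out$ILCR <- x$ilcr_total
  out
}

#' @export
print.risk_result <- function(x, ...) {
  cat(sprintf("<risk_result> site '%s'\n", x$site_id))
  cat("  THQ by pathway:",
      paste(sprintf("%s %s", names(x$thq), format_risk(x$thq)), collapse = ", "), "\n")
  cat(sprintf("  HI = %s (%s non-cancer risk)\n", format_risk(x$hi), x$classification$noncancer))
  cat(sprintf("  total ILCR = %s (%s cancer risk)\n",
              format_risk(x$ilcr_total), x$classification$cancer))
  if (length(x$warnings) > 0L) cat("  notes:", length(x$warnings), "metal-pathway skips\n")
  invisible(x)
}

check_cs <- function(Cs) {
  if (!is.numeric(Cs) || any(!is.finite(Cs)) || any(Cs < 0)) {
    stop("Cs must be finite and >= 0 (mg/kg)", call. = FALSE)
  }
}

pick_at <- function(p, averaging) {
  stopifnot(inherits(p, "exposure_parameters"))
  averaging <- match.arg(averaging, c("nc", "ca"))
  if (averaging == "nc") p$AT_nc else p$AT_ca
}
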