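#' Inhalation reference dose from a reference concentration
#'
#' Converts an inhalation reference concentration RfC (mg/m3) into a
#' reference dose RfD (mg/kg-day):
#'
#' \deqn{RfD = RfC \times InhR / BW}
#'
#' In `"receptor"` mode the receptor's own inhalation rate and body weight
#' are used; in `"fixed"` mode the adult values are used for every receptor
#' (see the `mode` discussion in [assess_sites()]).
#'
#' @param rfc Reference concentration(s), mg/m3; vectorized.
#' @param profile One-row exposure profile of the receptor.
#' @param rfd_mode `"receptor"` (default) or `"fixed"`.
#' @param adult_profile Profile used in `"fixed"` mode; defaults to the
#'   bundled adult profile.
#' @return RfD in mg/kg-day.
#' @export
#' @examples
#' adult <- get_profile(load_exposure_profiles(), "adult")
#' reference_dose(0.1, adult)   # 0.1 * 15 / 80
reference_dose <- function(rfc, profile, rfd_mode = c("receptor", "fixed"),
                           adult_profile = NULL) {
  rfd_mode <- match.arg(rfd_mode)
  if (any(rfc < 0, na.rm = TRUE)) stop("negative RfC")
  p <- profile
  if (rfd_mode == "fixed") {
    p <- if (is.null(adult_profile)) {
      get_profile(load_exposure_profiles(), "adult")
    } else {
      adult_profile
    }
  }
  rfc * p$inhr / p$bw
}

#' Hazard quotient of one element
#'
#' Ratio of the non-carcinogenic average daily intake to the reference
#' dose: `HQ = ADI / RfD`. A zero or negative RfD is an error here; in the
#' pipeline such elements are excluded upstream with a warning so reports
#' never contain infinities.
#'
#' @param adi Non-carcinogenic ADI, mg/kg-day; vectorized.
#' @param rfd Reference dose, mg/kg-day (same length or scalar).
#' @return Dimensionless hazard quotient(s).
#' @export
hazard_quotient <- function(adi, rfd) {
  if (any(adi < 0)) stop("negative ADI")
  if (any(!(rfd > 0))) stop("RfD must be > 0 for a hazard quotient")
  adi / rfd
}

#' Hazard index
#'
#' Sum of the hazard quotients of all assessed elements. The empty sum is
#' returned as 0 with a warning (nothing was assessable).
#'
#' @param hqs Numeric vector of hazard quotients, all >= 0.
#' @return The hazard index (dimensionless).
#' @export
hazard_index <- function(hqs) {
  if (length(hqs) == 0) {
    warning("no hazard quotients; hazard index is 0")
    return(0)
  }
  if (any(hqs < 0)) stop("negative hazard quotient")
  sum(hqs)
}

#' Incremental lifetime cancer risk of one element
#'
#' Converts the carcinogenic average daily intake back to an equivalent air
#' concentration and applies the inhalation unit risk:
#'
#' \deqn{CR = ADI \times IUR \times 10^3 \times BW / InhR}
#'
#' (the 10^3 converts mg to ug). In `"receptor"` mode BW/InhR come from the
#' receptor's own profile, which makes CR algebraically independent of BW
#' and InhR (they cancel against the intake equation); in `"fixed"` mode the
#' adult BW/InhR factor is applied to every receptor.
#'
#' @param adi Carcinogenic ADI, mg/kg-day; vectorized.
#' @param iur Inhalation unit risk, (ug/m3)^-1.
#' @param profile One-row exposure profile of the receptor.
#' @param cr_mode `"receptor"` (default) or `"fixed"`.
#' @param adult_profile Profile used in `"fixed"` mode; defaults to the
#'   bundled adult profile.
#' @return Dimensionless excess lifetime cancer risk(s).
#' @export
cancer_risk <- function(adi, iur, profile, cr_mode = c("receptor", "fixed"),
                        adult_profile = NULL) {
  cr_mode <- match.arg(cr_mode)
  if (any(adi < 0)) stop("negative ADI")
  if (any(iur < 0, na.rm = TRUE)) stop("negative IUR")
  p <- profile
  if (cr_mode == "fixed") {
    p <- if (is.null(adult_profile)) {
      get_profile(load_exposure_profiles(), "adult")
    } else {
      adult_profile
    }
  }
  adi * iur * 1e3 * p$bw / p$inhr
}

#' Total cancer risk
#'
#' Sum of the element-wise cancer risks (standard additivity across
#' carcinogens). The empty sum is 0 with a warning.
#'
#' @param crs Numeric vector of cancer risks, all >= 0.
#' @return Total dimensionless cancer risk.
#' @export
total_cancer_risk <- function(crs) {
  if (length(crs) == 0) {
    warning("no cancer risks; total is 0")
    return(0)
  }
  if (any(crs < 0)) stop("negative cancer risk")
  sum(crs)
}

#' Classify a hazard index
#'
#' `"risk"` when HI strictly exceeds the limit (default 1), otherwise
#' `"no_risk"`. HI exactly at the limit is `"no_risk"` (strict inequality).
#'
#' @param hi Hazard index (vectorized), >= 0.
#' @param thresholds A [risk_thresholds()] object.
#' @return Character vector of labels.
#' @export
classify_hazard_index <- function(hi, thresholds = risk_thresholds()) {
  if (any(hi < 0)) stop("negative hazard index")
  ifelse(hi > thresholds$hi_limit, "risk", "no_risk")
}

#' Classify a cancer risk
#'
#' `"acceptable"` at or below the acceptable level (default 1e-6, "at or
#' lower than"), `"tolerable"` above it up to and including the tolerable
#' upper bound (default 1e-4), `"unacceptable"` beyond.
#'
#' @param cr Cancer risk (vectorized), >= 0.
#' @param thresholds A [risk_thresholds()] object.
#' @return Character vector of labels.
#' @export
classify_cancer_risk <- function(cr, thresholds = risk_thresholds()) {
  if (any(cr < 0)) stop("negative cancer risk")
  ifelse(cr <= thresholds$cr_acceptable, "acceptable",
         ifelse(cr <= thresholds$cr_tolerable_upper, "tolerable",
                "unacceptable"))
}

#' Site-by-site inhalation health risk assessment
#'
#' Runs the full assessment pipeline on a multi-site dust composition table
#' and a PM10 series: exposure-point concentration, chromium speciation,
#' per-element average daily intakes (both averaging times), hazard
#' quotients and hazard index, element-wise and total cancer risk, and
#' classification against decision thresholds — for every sample and
#' receptor.
#'
#' Two computation modes are provided:
#'
#' * `"strict"` applies the intake, reference-dose and risk equations
#'   literally with each receptor's own parameters. Under the standard
#'   parameter set (where the non-carcinogenic averaging time equals
#'   ED x 365 for each receptor) the hazard quotient is then
#'   receptor-independent, and BW and InhR cancel out of the cancer risk.
#' * `"replicate"` reproduces the internal conventions evident in published
#'   site tables for this kind of assessment, whose child/adult ratios
#'   (HI ratio 40/9 = 4.444, CR ratio = 11.966) are inconsistent with the
#'   literal equations: a single adult-derived reference dose is used for
#'   both receptors, the adult BW/InhR factor is applied in the cancer-risk
#'   equation for both receptors, and the child's carcinogenic averaging
#'   time is set equal to its non-carcinogenic one. Neither mode is labelled
#'   "correct"; `mode` is echoed in the report.
#'
#' Elements with no reference concentration are omitted from HI, and
#' elements with no unit risk from CR — each omission is counted and
#' reported with a warning rather than contributing a silent zero.
#'
#' @param comp Composition table (long format; see
#'   [read_composition_table()]). Total chromium (element `"Cr"`) is
#'   speciated into Cr(VI)/Cr(III) before assessment.
#' @param pm PM series data frame, an `"epc"` object, or a single PM10
#'   concentration (ug/m3). A series is reduced with
#'   [exposure_point_concentration()] once and shared across all sites.
#' @param profiles Exposure profiles; default bundled adult + child.
#' @param tox Toxicity table; default bundled snapshot.
#' @param thresholds Decision thresholds; default [risk_thresholds()].
#' @param mode `"strict"` (default) or `"replicate"`.
#' @param epc_method UCL method passed to [exposure_point_concentration()].
#' @param cr_ratio Cr(VI):Cr(III) speciation weights, default `c(1, 6)`.
#' @return An object of class `"risk_report"`: a list with `sites`
#'   (per sample x receptor HI, total CR and bands), `elements`
#'   (per-element ADI/HQ/CR detail), `epc`, `mode`, `thresholds`,
#'   `profiles`, and `skipped` (elements lacking reference values).
#' @export
#' @examples
#' camp <- generate_campaign(generator_config(seed = 1))
#' rep <- assess_sites(camp$composition, camp$pm)
#' rep
assess_sites <- function(comp, pm,
                         profiles = load_exposure_profiles(),
                         tox = load_toxicity_table(),
                         thresholds = risk_thresholds(),
                         mode = c("strict", "replicate"),
                         epc_method = "t_ucl95",
                         cr_ratio = c(1, 6)) {
  mode <- match.arg(mode)
  comp <- speciate_composition(validate_composition(comp), ratio = cr_ratio)
  profiles <- validate_exposure_profiles(profiles)
  tox <- validate_toxicity_table(tox)

  epc <- if (inherits(pm, "epc")) {
    pm
  } else if (is.data.frame(pm)) {
    exposure_point_concentration(validate_pm_series(pm)$pm10,
                                 method = epc_method)
  } else if (is.numeric(pm) && length(pm) == 1) {
    structure(list(value = pm, n = 1L, method = "given", mean = pm),
              class = "epc")
  } else {
    stop("pm must be a PM series, an epc object, or a single concentration")
  }

  assessable <- intersect(unique(comp$element), tox$element)
  if (!length(assessable)) {
    stop("no overlap between composition elements and toxicity table")
  }
  no_ref <- setdiff(unique(comp$element), tox$element)
  if (length(no_ref)) {
    warning(length(no_ref), " element(s) without any reference value ",
            "omitted from the assessment: ", paste(no_ref, collapse = ", "))
  }

  adult <- get_profile(profiles, "adult")
  sub_mode <- if (mode == "strict") "receptor" else "fixed"

  elements <- list()
  sites <- list()
  for (r in seq_len(nrow(profiles))) {
    prof <- profiles[r, , drop = FALSE]
    # replicate convention: the child's lifetime AT collapses to its nc
    # value (ED x 365); the adult keeps the full 70-year averaging time
    prof_ca <- prof
    if (mode == "replicate" && prof$receptor == "child") {
      prof_ca$at_ca <- prof$at_nc
    }
    for (s in unique(comp$sample)) {
      rows <- comp[comp$sample == s & comp$element %in% assessable, ]
      ti <- match(rows$element, tox$element)
      rfc <- tox$rfc[ti]
      iur <- tox$iur[ti]
      adi_nc <- average_daily_intake(rows$concentration, epc, prof, "nc")
      adi_ca <- average_daily_intake(rows$concentration, epc, prof_ca, "ca")
      rfd <- reference_dose(rfc, prof, rfd_mode = sub_mode,
                            adult_profile = adult)
      has_rfd <- !is.na(rfd) & rfd > 0
      hq <- rep(NA_real_, nrow(rows))
      hq[has_rfd] <- hazard_quotient(adi_nc[has_rfd], rfd[has_rfd])
      has_iur <- !is.na(iur)
      cr <- rep(NA_real_, nrow(rows))
      cr[has_iur] <- cancer_risk(adi_ca[has_iur], iur[has_iur], prof,
                                 cr_mode = sub_mode, adult_profile = adult)
      elements[[length(elements) + 1L]] <- data.frame(
        sample = s, city = rows$city, receptor = prof$receptor,
        element = rows$element, concentration = rows$concentration,
        adi_nc = adi_nc, adi_ca = adi_ca, rfd = rfd, hq = hq, cr = cr,
        stringsAsFactors = FALSE
      )
      hi <- hazard_index(hq[!is.na(hq)])
      crt <- total_cancer_risk(cr[!is.na(cr)])
      sites[[length(sites) + 1L]] <- data.frame(
        sample = s, city = rows$city[1], receptor = prof$receptor,
        hi = hi, hi_band = classify_hazard_index(hi, thresholds),
        cr_total = crt, cr_band = classify_cancer_risk(crt, thresholds),
        stringsAsFactors = FALSE
      )
    }
  }
  elements <- do.call(rbind, elements)
  sites <- do.call(rbind, sites)
  rownames(elements) <- rownames(sites) <- NULL

  n_no_rfc <- length(setdiff(assessable,
                             tox$element[!is.na(tox$rfc) & tox$rfc > 0]))
  n_no_iur <- length(setdiff(assessable, tox$element[!is.na(tox$iur)]))
  if (n_no_rfc > 0) {
    warning(n_no_rfc, " assessable element(s) lack a usable RfC ",
            "and are omitted from the hazard index")
  }
  if (n_no_iur > 0) {
    warning(n_no_iur, " assessable element(s) lack an IUR ",
            "and are omitted from the cancer risk")
  }

  structure(
    list(sites = sites, elements = elements, epc = epc, mode = mode,
         thresholds = thresholds, profiles = profiles,
         skipped = list(no_reference = no_ref,
                        n_no_rfc = n_no_rfc, n_no_iur = n_no_iur)),
    class = "risk_report"
  )
}

#' @export
print.risk_report <- function(x, ...) {
  cat("Inhalation health risk assessment (mode: ", x$mode, ")\n", sep = "")
  cat("  PM10 exposure-point concentration: ",
      format(x$epc$value, digits = 5), " ug/m3 (", x$epc$method, ")\n",
      sep = "")
  cat("  ", length(unique(x$sites$sample)), " site(s), ",
      nrow(x$profiles), " receptor(s), ",
      length(unique(x$elements$element)), " assessed element(s)\n\n",
      sep = "")
  df <- x$sites
  df$hi <- signif(df$hi, 3)
  df$cr_total <- signif(df$cr_total, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.risk_report <- function(object, ...) {
  s <- object$sites
  el <- object$elements
  hq_by_el <- vapply(split(el$hq, el$element),
                     function(v) mean(v, na.rm = TRUE), numeric(1))
  cr_by_el <- vapply(split(el$cr, el$element),
                     function(v) mean(v, na.rm = TRUE), numeric(1))
  out <- list(
    mode = object$mode,
    epc = object$epc,
    n_sites = length(unique(s$sample)),
    hi_range = tapply(s$hi, s$receptor, range),
    n_hi_above = tapply(s$hi_band == "risk", s$receptor, sum),
    cr_band_counts = table(s$receptor, s$cr_band),
    top_hq = sort(hq_by_el[!is.nan(hq_by_el)], decreasing = TRUE),
    top_cr = sort(cr_by_el[!is.nan(cr_by_el)], decreasing = TRUE)
  )
  class(out) <- "summary.risk_report"
  out
}

#' @export
print.summary.risk_report <- function(x, ...) {
  cat("Risk assessment summary (mode: ", x$mode, ")\n", sep = "")
  cat("  sites: ", x$n_sites, "; PM10 EPC: ",
      format(x$epc$value, digits = 5), " ug/m3\n", sep = "")
  for (r in names(x$hi_range)) {
    cat("  ", r, ": HI in [", paste(signif(x$hi_range[[r]], 3),
                                    collapse = ", "),
        "], ", x$n_hi_above[[r]], " site(s) above the limit\n", sep = "")
  }
  cat("  cancer-risk bands by receptor:\n")
  print(x$cr_band_counts)
  cat("  leading hazard-quotient contributors: ",
      paste(utils::head(names(x$top_hq), 3), collapse = ", "), "\n", sep = "")
  cat("  leading cancer-risk contributors: ",
      paste(utils::head(names(x$top_cr), 3), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.risk_report <- function(x, ...) x$sites

#' Plot a risk report
#'
#' Barplots of the hazard index and total cancer risk per site and
#' receptor, with the decision thresholds drawn as horizontal lines (the
#' cancer-risk panel is on a log scale).
#'
#' @param x A `risk_report` object.
#' @param ... Passed to [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.risk_report <- function(x, ...) {
  s <- x$sites
  samples <- unique(s$sample)
  receptors <- unique(s$receptor)
  hi <- t(vapply(receptors, function(r)
    s$hi[s$receptor == r][match(samples, s$sample[s$receptor == r])],
    numeric(length(samples))))
  cr <- t(vapply(receptors, function(r)
    s$cr_total[s$receptor == r][match(samples, s$sample[s$receptor == r])],
    numeric(length(samples))))
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::barplot(hi, beside = TRUE, names.arg = samples,
                    legend.text = receptors, ylab = "Hazard index",
                    main = paste0("Hazard index (mode: ", x$mode, ")"), ...)
  graphics::abline(h = x$thresholds$hi_limit, lty = 2, col = "red")
  graphics::barplot(cr, beside = TRUE, names.arg = samples, log = "y",
                    ylab = "Total cancer risk",
                    main = "Total cancer risk", ...)
  graphics::abline(h = c(x$thresholds$cr_acceptable,
                         x$thresholds$cr_tolerable_upper),
                   lty = 2, col = c("orange", "red"))
  invisible(x)
}
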