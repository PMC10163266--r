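#' dustrisk: inhalation risk and endpoint impact assessment for dust storms
#'
#' Tools for US EPA-style inhalation risk assessment of trace elements in
#' dust-storm particles (average daily intake, hazard quotient/index,
#' incremental lifetime cancer risk), chromium speciation, a 95% upper
#' confidence limit exposure-point concentration for PM10, WHO guideline
#' exceedance summaries, ReCiPe-style endpoint characterization, and a
#' seeded synthetic campaign generator.
#'
#' The main entry points are [assess_sites()] for health risk,
#' [characterize_impacts()] for endpoint impacts, and [generate_campaign()]
#' for synthetic data.
#'
#' @keywords internal
"_PACKAGE"

# Closed set of endpoint impact categories (hierarchist endpoint level).
.impact_categories <- c(
  "human carcinogenic toxicity",
  "human non-carcinogenic toxicity",
  "freshwater ecotoxicity",
  "marine ecotoxicity",
  "terrestrial ecotoxicity"
)

.human_categories <- .impact_categories[1:2]
.eco_categories <- .impact_categories[3:5]

#' Endpoint impact categories
#'
#' The closed set of five endpoint-level impact categories used by
#' [characterize_impacts()]: two human-health categories (unit DALY) and
#' three ecotoxicity categories (unit species.yr).
#'
#' @return Character vector of length five.
#' @export
#' @examples
#' impact_categories()
impact_categories <- function() .impact_categories

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "dustrisk")
  if (!nzchar(path)) stop("bundled file not found: ", file)
  path
}

#' Load receptor exposure profiles
#'
#' Reads exposure-parameter profiles (inhalation rate, exposure frequency and
#' duration, body weight, averaging times) for one or more receptor classes.
#' With no `path`, returns the bundled defaults for an adult and a child
#' (2-6 years) receptor, following standard US EPA residential exposure
#' recommendations: adult InhR 15 m3/day, EF 350 days/yr, ED 26 yr, BW 80 kg,
#' non-carcinogenic AT 9490 days, carcinogenic AT 25550 days; child InhR
#' 12.5 m3/day, ED 6 yr, BW 15 kg, non-carcinogenic AT 2190 days.
#'
#' @param path Optional path to a CSV file with columns
#'   `receptor,inhr,ef,ed,bw,at_nc,at_ca`. Units: m3/day, days/year, years,
#'   kg, days, days.
#' @return A data frame of validated profiles, one row per receptor.
#' @export
#' @examples
#' load_exposure_profiles()
load_exposure_profiles <- function(path = NULL) {
  if (is.null(path)) path <- .extdata("exposure_profiles.csv")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_exposure_profiles(df)
}

#' Validate a data frame of exposure profiles
#'
#' Checks the schema and invariants of an exposure-profile table: all
#' numeric parameters strictly positive, exposure frequency at most 366
#' days/year, receptor labels unique.
#'
#' @param df Data frame with columns `receptor,inhr,ef,ed,bw,at_nc,at_ca`.
#' @return The validated data frame, invisibly classed as plain data frame.
#' @export
validate_exposure_profiles <- function(df) {
  needed <- c("receptor", "inhr", "ef", "ed", "bw", "at_nc", "at_ca")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("exposure profile table lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  df <- df[needed]
  num <- needed[-1]
  for (col in num) {
    v <- df[[col]]
    if (!is.numeric(v) || anyNA(v)) {
      stop("exposure profile column '", col, "' must be numeric and complete")
    }
    bad <- which(v <= 0)
    if (length(bad)) {
      stop("exposure profile '", df$receptor[bad[1]], "': ", col,
           " must be > 0 (row ", bad[1], ")")
    }
  }
  if (any(df$ef > 366)) {
    stop("exposure frequency ef must be <= 366 days/year")
  }
  if (anyDuplicated(df$receptor)) {
    stop("duplicate receptor label(s): ",
         paste(unique(df$receptor[duplicated(df$receptor)]), collapse = ", "))
  }
  df
}

#' Look up one receptor's profile
#'
#' @param profiles Profile data frame from [load_exposure_profiles()].
#' @param receptor Receptor label, e.g. `"adult"`.
#' @return A one-row data frame.
#' @export
get_profile <- function(profiles, receptor) {
  i <- match(receptor, profiles$receptor)
  if (is.na(i)) stop("no profile for receptor '", receptor, "'")
  profiles[i, , drop = FALSE]
}

#' Write exposure profiles to CSV
#'
#' @param profiles Profile data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_exposure_profiles <- function(profiles, path) {
  profiles <- validate_exposure_profiles(profiles)
  utils::write.csv(profiles, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Load an inhalation toxicity reference table
#'
#' Reads per-element inhalation reference values: the reference
#' concentration RfC (mg/m3, non-carcinogenic benchmark) and the inhalation
#' unit risk IUR ((ug/m3)^-1, carcinogenic slope). Every element must carry
#' at least one of the two. With no `path`, returns a bundled, pinned
#' demonstration snapshot of Regional Screening Level style values for the
#' elements of concern in heavy-metal dust (Cr(VI), Cr(III), As, Co, Ni, Mn,
#' Zn, Cu, Pb, Cd); the `source` column records the provenance of each
#' value, including those route-extrapolated from oral reference doses for
#' demonstration. Chromium appears only as the two species Cr(VI) and
#' Cr(III); total chromium has no entry and must be speciated first (see
#' [speciate_chromium()]).
#'
#' @param path Optional CSV path with columns `element,rfc,iur,source`.
#'   Missing values are written as `NA`.
#' @return Data frame of validated toxicity records.
#' @export
#' @examples
#' tox <- load_toxicity_table()
#' tox[tox$element == "Cr(VI)", ]
load_toxicity_table <- function(path = NULL) {
  if (is.null(path)) path <- .extdata("toxicity_air_snapshot.csv")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_toxicity_table(df)
}

#' Validate a toxicity reference table
#'
#' @param df Data frame with columns `element,rfc,iur` (and optionally
#'   `source`).
#' @return The validated data frame.
#' @export
validate_toxicity_table <- function(df) {
  needed <- c("element", "rfc", "iur")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("toxicity table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (!"source" %in% names(df)) df$source <- NA_character_
  if (any(!nzchar(df$element) | is.na(df$element))) {
    stop("toxicity table has empty element identifiers")
  }
  dup <- unique(df$element[duplicated(df$element)])
  if (length(dup)) {
    stop("duplicate toxicity rows for element(s): ",
         paste(dup, collapse = ", "))
  }
  both_absent <- is.na(df$rfc) & is.na(df$iur)
  if (any(both_absent)) {
    stop("element(s) with neither RfC nor IUR: ",
         paste(df$element[both_absent], collapse = ", "))
  }
  if (any(df$rfc < 0, na.rm = TRUE)) stop("negative RfC in toxicity table")
  if (any(df$iur < 0, na.rm = TRUE)) stop("negative IUR in toxicity table")
  df[c("element", "rfc", "iur", "source")]
}

#' Write a toxicity table to CSV
#'
#' @param tox Toxicity data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_toxicity_table <- function(tox, path) {
  tox <- validate_toxicity_table(tox)
  utils::write.csv(tox, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Load endpoint characterization factors
#'
#' Reads per-element endpoint characterization factors: impact per kg of
#' element emitted to air, in DALY/kg for the two human-health categories
#' and species.yr/kg for the three ecotoxicity categories. Categories must
#' belong to the closed five-category set of [impact_categories()]. With no
#' `path`, returns a bundled synthetic demonstration set
#' (`characterization_factors_synthetic.csv`) whose values are
#' order-of-magnitude plausible but NOT taken from any authoritative
#' endpoint factor table; real analyses should supply their own factors.
#'
#' @param path Optional CSV path with columns `element,category,factor`.
#' @return Data frame of validated factors (possibly zero rows).
#' @export
load_characterization_factors <- function(path = NULL) {
  if (is.null(path)) path <- .extdata("characterization_factors_synthetic.csv")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_characterization_factors(df)
}

#' Validate a characterization-factor table
#'
#' @param df Data frame with columns `element,category,factor`.
#' @return The validated data frame.
#' @export
validate_characterization_factors <- function(df) {
  needed <- c("element", "category", "factor")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("factor table lacks column(s): ", paste(missing, collapse = ", "))
  }
  df <- df[needed]
  if (nrow(df) == 0) return(df)
  unknown <- setdiff(unique(df$category), .impact_categories)
  if (length(unknown)) {
    stop("unknown impact categor", if (length(unknown) > 1) "ies: " else "y: ",
         paste(unknown, collapse = ", "))
  }
  if (any(!is.finite(df$factor))) {
    stop("non-finite characterization factor(s)")
  }
  if (anyDuplicated(df[c("element", "category")])) {
    stop("duplicate (element, category) rows in factor table")
  }
  df
}

#' Write characterization factors to CSV
#'
#' @param factors Factor data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_characterization_factors <- function(factors, path) {
  factors <- validate_characterization_factors(factors)
  utils::write.csv(factors, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Risk decision thresholds
#'
#' Regulatory decision values used to classify hazard indices and cancer
#' risks. Defaults: hazard index limit 1 (non-carcinogenic risk flagged when
#' HI exceeds 1), cancer risk acceptable at or below 1e-6 (one in a
#' million), and a regulatory tolerable band extending up to 1e-4.
#'
#' @param hi_limit Hazard-index decision value (dimensionless), > 0.
#' @param cr_acceptable Cancer risk at or below which risk is acceptable.
#' @param cr_tolerable_upper Upper bound of the tolerable band;
#'   must exceed `cr_acceptable`.
#' @return A list with class `"risk_thresholds"`.
#' @export
#' @examples
#' risk_thresholds()
risk_thresholds <- function(hi_limit = 1,
                            cr_acceptable = 1e-6,
                            cr_tolerable_upper = 1e-4) {
  if (!(hi_limit > 0)) stop("hi_limit must be > 0")
  if (!(cr_acceptable > 0 && cr_acceptable < cr_tolerable_upper)) {
    stop("need 0 < cr_acceptable < cr_tolerable_upper")
  }
  structure(
    list(hi_limit = hi_limit, cr_acceptable = cr_acceptable,
         cr_tolerable_upper = cr_tolerable_upper),
    class = "risk_thresholds"
  )
}

#' @export
print.risk_thresholds <- function(x, ...) {
  cat("Risk decision thresholds\n")
  cat("  hazard index limit: ", format(x$hi_limit), "\n", sep = "")
  cat("  cancer risk acceptable at or below: ",
      format(x$cr_acceptable, scientific = TRUE), "\n", sep = "")
  cat("  tolerable band upper bound: ",
      format(x$cr_tolerable_upper, scientific = TRUE), "\n", sep = "")
  invisible(x)
}

#' Published site-level risk summary for an 11-site dust-storm campaign
#'
#' Returns the published per-site hazard index and total cancer risk values
#' (adult and child receptors) for the 11-site Jazmurian basin dust-storm
#' campaign bundled with the package. Used for ratio-consistency checks.
#'
#' @return Data frame with columns `city, sample, hi_adult, hi_child,
#'   cr_adult, cr_child`.
#' @export
published_site_risk <- function() {
  utils::read.csv(.extdata("jazmurian_site_risk.csv"),
                  stringsAsFactors = FALSE)
}

#' Published endpoint impact table for the same campaign
#'
#' Returns the published endpoint characterization results (per gram of
#' particles) for the 11-site Jazmurian campaign: mantissas per category and
#' sample, with the decimal `scale` of each row. Used for internal
#' additivity checks of the human-health total.
#'
#' @return Data frame with columns `category, unit, scale, D1...D11`.
#' @export
published_endpoint_impacts <- function() {
  utils::read.csv(.extdata("jazmurian_endpoint_impacts.csv"),
                  check.names = FALSE, stringsAsFactors = FALSE)
}
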