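#' Read a long-format dust composition table
#'
#' Reads per-sample element concentrations in dust (mg element per kg dust)
#' from a long/tidy CSV with columns `sample,city,element,concentration`.
#' Concentration cells may be censored with a `<` prefix (e.g. `"<1"`,
#' meaning below the limit of detection); such cells are resolved according
#' to `lod_policy` and flagged in the returned `below_lod` column:
#'
#' * `"half"` (default): LOD/2, the common risk-assessment convention;
#' * `"zero"`: 0;
#' * `"keep"`: the LOD itself.
#'
#' The LOD for a censored cell is the number after `<` when present,
#' otherwise the `lod` argument. An explicit logical `below_lod` column is
#' treated as provenance only: its numeric concentrations are trusted
#' as-is (so tables written by [write_composition_table()] re-load
#' unchanged) and the flag is carried through.
#'
#' @param path CSV file path.
#' @param lod Default limit of detection (mg/kg) for cells censored as
#'   plain `"<"` or via a logical `below_lod` column. Default 1.
#' @param lod_policy One of `"half"`, `"zero"`, `"keep"`.
#' @return A data frame with columns
#'   `sample, city, element, concentration, below_lod`.
#' @export
read_composition_table <- function(path, lod = 1,
                                   lod_policy = c("half", "zero", "keep")) {
  lod_policy <- match.arg(lod_policy)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  needed <- c("sample", "element", "concentration")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("composition table lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  if (!"city" %in% names(df)) df$city <- NA_character_
  raw <- trimws(df$concentration)
  censored <- startsWith(raw, "<")
  lod_val <- rep(lod, nrow(df))
  explicit <- censored & nzchar(sub("^<", "", raw))
  lod_val[explicit] <- as.numeric(sub("^<", "", raw[explicit]))
  conc <- suppressWarnings(as.numeric(raw))
  conc[censored] <- switch(lod_policy,
    half = lod_val[censored] / 2,
    zero = 0,
    keep = lod_val[censored]
  )
  if (anyNA(conc)) {
    bad <- which(is.na(conc))[1]
    stop("unparseable concentration '", raw[bad], "' at row ", bad)
  }
  # an explicit below_lod column is provenance only: the numeric value is
  # trusted (e.g. re-reading our own writer's output); the policy applies
  # to "<"-censored cells alone
  below <- censored
  if ("below_lod" %in% names(df)) {
    flagged <- tolower(trimws(df$below_lod)) %in% c("true", "1", "yes")
    below <- below | flagged
  }
  out <- data.frame(
    sample = df$sample, city = df$city, element = df$element,
    concentration = conc, below_lod = below,
    stringsAsFactors = FALSE
  )
  validate_composition(out)
}

#' Read a wide-format composition table
#'
#' Convenience reader for tables with one row per sample and one column per
#' element (first columns `sample` and optionally `city`); reshapes to the
#' long layout of [read_composition_table()]. Censoring and LOD policy work
#' identically.
#'
#' @inheritParams read_composition_table
#' @return Long-format composition data frame.
#' @export
read_composition_wide <- function(path, lod = 1,
                                  lod_policy = c("half", "zero", "keep")) {
  lod_policy <- match.arg(lod_policy)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  if (!"sample" %in% names(df)) stop("wide composition table needs 'sample'")
  id_cols <- intersect(c("sample", "city"), names(df))
  el_cols <- setdiff(names(df), id_cols)
  if (!length(el_cols)) stop("wide composition table has no element columns")
  long <- do.call(rbind, lapply(el_cols, function(el) {
    data.frame(sample = df$sample,
               city = if ("city" %in% id_cols) df$city else NA_character_,
               element = el, concentration = df[[el]],
               stringsAsFactors = FALSE)
  }))
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  utils::write.csv(long, tmp, row.names = FALSE)
  read_composition_table(tmp, lod = lod, lod_policy = lod_policy)
}

#' Validate a composition table
#'
#' Invariants: concentrations numeric, finite and non-negative;
#' (sample, element) pairs unique.
#'
#' @param comp Composition data frame
#'   (`sample, city, element, concentration`, optional `below_lod`).
#' @return The validated data frame (with a `below_lod` column).
#' @export
validate_composition <- function(comp) {
  needed <- c("sample", "element", "concentration")
  missing <- setdiff(needed, names(comp))
  if (length(missing)) {
    stop("composition table lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  if (!"city" %in% names(comp)) comp$city <- NA_character_
  if (!"below_lod" %in% names(comp)) comp$below_lod <- FALSE
  if (!is.numeric(comp$concentration) || anyNA(comp$concentration) ||
      any(!is.finite(comp$concentration))) {
    stop("concentrations must be finite numbers")
  }
  if (any(comp$concentration < 0)) {
    bad <- comp[comp$concentration < 0, ][1, ]
    stop("negative concentration for (", bad$sample, ", ", bad$element, ")")
  }
  key <- paste(comp$sample, comp$element, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- comp[duplicated(key), c("sample", "element")][1, ]
    stop("duplicate (sample, element) pair: (",
         dup$sample, ", ", dup$element, ")")
  }
  comp[c("sample", "city", "element", "concentration", "below_lod")]
}

#' Write a composition table to CSV
#'
#' @param comp Composition data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_composition_table <- function(comp, path) {
  comp <- validate_composition(comp)
  utils::write.csv(comp, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a daily PM2.5/PM10 series
#'
#' Reads a CSV with columns `date,pm25,pm10` (ISO-8601 dates, ug/m3).
#' Rows are returned ordered by date; unordered input is sorted with a
#' warning. Gaps between dates are permitted and reported via a message.
#'
#' @param path CSV file path.
#' @return Data frame with `date` (class `Date`), `pm25`, `pm10`.
#' @export
read_pm_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("date", "pm25", "pm10")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("PM series lacks column(s): ", paste(missing, collapse = ", "))
  }
  d <- as.Date(df$date, format = "%Y-%m-%d")
  if (anyNA(d)) {
    stop("unparseable date '", df$date[which(is.na(d))[1]], "' (need ISO-8601)")
  }
  df$date <- d
  validate_pm_series(df)
}

#' Validate a PM series
#'
#' Invariants: non-negative concentrations, unique dates; rows returned in
#' date order (sorting with a warning when the input is unordered).
#'
#' @param pm Data frame with `date`, `pm25`, `pm10`.
#' @return The validated, ordered data frame.
#' @export
validate_pm_series <- function(pm) {
  needed <- c("date", "pm25", "pm10")
  missing <- setdiff(needed, names(pm))
  if (length(missing)) {
    stop("PM series lacks column(s): ", paste(missing, collapse = ", "))
  }
  pm <- pm[needed]
  for (col in c("pm25", "pm10")) {
    v <- pm[[col]]
    if (!is.numeric(v) || anyNA(v)) stop(col, " must be numeric and complete")
    bad <- which(v < 0)
    if (length(bad)) {
      stop("negative ", col, " on ", format(pm$date[bad[1]]))
    }
  }
  if (anyDuplicated(pm$date)) {
    stop("duplicate date(s) in PM series: ",
         format(pm$date[duplicated(pm$date)][1]))
  }
  if (is.unsorted(pm$date)) {
    warning("PM series dates were unordered; sorting by date")
    pm <- pm[order(pm$date), ]
    rownames(pm) <- NULL
  }
  if (nrow(pm) > 1) {
    gaps <- diff(as.integer(pm$date))
    n_gap <- sum(gaps > 1)
    if (n_gap > 0) {
      message(n_gap, " gap(s) in the daily PM series")
    }
  }
  pm
}

#' Write a PM series to CSV
#'
#' @param pm PM series data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pm_series <- function(pm, path) {
  pm <- validate_pm_series(pm)
  pm$date <- format(pm$date, "%Y-%m-%d")
  utils::write.csv(pm, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summarize exceedance of air-quality guidelines
#'
#' Counts days on which PM2.5 and PM10 exceed 24-hour guideline values, and
#' reports means and maxima of each series. Defaults are the WHO 2021 24-h
#' guidelines: 15 ug/m3 for PM2.5 and 45 ug/m3 for PM10. Exceedance uses the
#' strict inequality `value > guideline`, so a day exactly at the guideline
#' does not count.
#'
#' @param pm PM series data frame (`date, pm25, pm10`).
#' @param guideline_pm25 24-h guideline for PM2.5, ug/m3. Default 15.
#' @param guideline_pm10 24-h guideline for PM10, ug/m3. Default 45.
#' @return A data frame with one row per pollutant: `pollutant, guideline,
#'   n_days, n_exceed, frac_exceed, mean, max`.
#' @export
#' @examples
#' pm <- data.frame(date = as.Date("2021-11-01") + 0:1,
#'                  pm25 = c(10, 20), pm10 = c(30, 90))
#' summarize_guideline_exceedance(pm)
summarize_guideline_exceedance <- function(pm, guideline_pm25 = 15,
                                           guideline_pm10 = 45) {
  pm <- validate_pm_series(pm)
  if (nrow(pm) == 0) stop("empty PM series")
  one <- function(values, pollutant, guideline) {
    n_ex <- sum(values > guideline)
    data.frame(pollutant = pollutant, guideline = guideline,
               n_days = length(values), n_exceed = n_ex,
               frac_exceed = n_ex / length(values),
               mean = mean(values), max = max(values),
               stringsAsFactors = FALSE)
  }
  rbind(one(pm$pm25, "pm25", guideline_pm25),
        one(pm$pm10, "pm10", guideline_pm10))
}

#' Write a risk report to CSV
#'
#' Serializes the site-level table of a [assess_sites()] report with a
#' deterministic column order. Numeric risk columns are stored at full
#' precision alongside 2-significant-figure display columns (the convention
#' used when such tables are published).
#'
#' @param report A `risk_report` object from [assess_sites()].
#' @param path Output file path.
#' @param what `"sites"` (default) writes the site-level summary;
#'   `"elements"` writes the element-level detail table.
#' @return `path`, invisibly.
#' @export
write_risk_report <- function(report, path, what = c("sites", "elements")) {
  what <- match.arg(what)
  if (!inherits(report, "risk_report")) stop("not a risk_report object")
  if (what == "elements") {
    utils::write.csv(report$elements, path, row.names = FALSE, quote = TRUE)
    return(invisible(path))
  }
  df <- report$sites
  disp <- function(x) ifelse(is.na(x), NA, signif(x, 2))
  out <- data.frame(
    sample = df$sample, city = df$city, receptor = df$receptor,
    hi = df$hi, hi_display = disp(df$hi), hi_band = df$hi_band,
    cr_total = df$cr_total, cr_total_display = disp(df$cr_total),
    cr_band = df$cr_band,
    mode = rep(report$mode, nrow(df)),
    c_pm10_used = rep(report$epc$value, nrow(df)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read back a serialized site-level risk report
#'
#' Inverse of [write_risk_report()] for the site-level table; full-precision
#' columns are used, display columns dropped.
#'
#' @param path CSV file written by [write_risk_report()].
#' @return Data frame with `sample, city, receptor, hi, hi_band, cr_total,
#'   cr_band, mode, c_pm10_used`.
#' @export
read_risk_report <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df[setdiff(names(df), c("hi_display", "cr_total_display"))]
}
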