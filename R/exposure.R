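#' Exposure-point concentration of a PM series
#'
#' Reduces a series of daily particulate concentrations to a single
#' exposure-point concentration (EPC), the "reasonable maximum exposure"
#' value carried through the intake equations. The default method is the
#' one-sided Student-t 95% upper confidence limit of the arithmetic mean,
#'
#' \deqn{EPC = \bar{x} + t_{0.95, n-1} \, s / \sqrt{n}}
#'
#' with sample standard deviation `s` — the baseline EPA recommendation for
#' approximately normal data. `"mean"` and `"max"` are available as
#' alternatives. By construction the t-UCL is never below the mean.
#'
#' @param values Numeric vector of concentrations (ug/m3), all >= 0.
#' @param method One of `"t_ucl95"` (default), `"mean"`, `"max"`.
#' @return An object of class `"epc"`: a list with `value` (ug/m3), `n`,
#'   `method` and `mean`.
#' @export
#' @examples
#' exposure_point_concentration(c(1, 2, 3))   # 2 + 2.92 / sqrt(3)
exposure_point_concentration <- function(values,
                                         method = c("t_ucl95", "mean", "max")) {
  method <- match.arg(method)
  if (length(values) == 0) stop("empty concentration series")
  if (anyNA(values) || any(!is.finite(values))) {
    stop("concentration series must be finite and complete")
  }
  if (any(values < 0)) stop("negative concentration in series")
  m <- mean(values)
  value <- switch(method,
    t_ucl95 = {
      n <- length(values)
      if (n < 2) stop("t_ucl95 needs n >= 2 (no dispersion estimate)")
      m + stats::qt(0.95, df = n - 1) * stats::sd(values) / sqrt(n)
    },
    mean = m,
    max = max(values)
  )
  structure(list(value = value, n = length(values), method = method,
                 mean = m),
            class = "epc")
}

#' @export
print.epc <- function(x, ...) {
  cat("Exposure-point concentration: ", format(x$value, digits = 5),
      " ug/m3 (", x$method, ", n = ", x$n, ", mean = ",
      format(x$mean, digits = 5), ")\n", sep = "")
  invisible(x)
}

#' Speciate total chromium into Cr(VI) and Cr(III)
#'
#' Splits a measured total-chromium concentration into hexavalent and
#' trivalent fractions by a fixed ratio. With the default 1:6 ratio the
#' hexavalent fraction is 1/7 of total chromium, a value representative of
#' crustal dust. Mass is conserved exactly: `cr6 + cr3` equals the input.
#'
#' @param total_cr Total chromium concentration(s), mg/kg; vectorized.
#' @param ratio Length-2 positive weights `c(cr6, cr3)`. Default `c(1, 6)`.
#' @return Data frame with columns `cr6` and `cr3` (mg/kg).
#' @export
#' @examples
#' speciate_chromium(7)         # cr6 = 1, cr3 = 6
#' speciate_chromium(70)        # cr6 = 10, cr3 = 60
speciate_chromium <- function(total_cr, ratio = c(1, 6)) {
  if (length(ratio) != 2 || any(!is.finite(ratio)) || any(ratio <= 0)) {
    stop("ratio must be two positive weights")
  }
  if (any(!is.finite(total_cr))) stop("total_cr must be finite")
  if (any(total_cr < 0)) stop("negative total chromium")
  cr6 <- total_cr * ratio[1] / sum(ratio)
  data.frame(cr6 = cr6, cr3 = total_cr - cr6)
}

#' Speciate chromium within a composition table
#'
#' Replaces each total-chromium row (element label `total_label`) of a
#' composition table by two rows, `Cr(VI)` and `Cr(III)`, split per
#' [speciate_chromium()]. Samples whose composition already reports the two
#' species are left untouched.
#'
#' @param comp Composition data frame.
#' @param ratio Cr(VI):Cr(III) weights, default `c(1, 6)`.
#' @param total_label Element label holding total chromium. Default `"Cr"`.
#' @return The composition table with chromium speciated.
#' @export
speciate_composition <- function(comp, ratio = c(1, 6), total_label = "Cr") {
  comp <- validate_composition(comp)
  is_total <- comp$element == total_label
  if (!any(is_total)) return(comp)
  cr <- comp[is_total, ]
  rest <- comp[!is_total, ]
  sp <- speciate_chromium(cr$concentration, ratio = ratio)
  mk <- function(label, conc) {
    data.frame(sample = cr$sample, city = cr$city, element = label,
               concentration = conc, below_lod = cr$below_lod,
               stringsAsFactors = FALSE)
  }
  out <- rbind(rest, mk("Cr(VI)", sp$cr6), mk("Cr(III)", sp$cr3))
  rownames(out) <- NULL
  validate_composition(out)
}

#' Average daily intake through inhalation
#'
#' Computes the average daily intake (ADI, mg per kg body weight per day) of
#' a trace element carried on inhaled particulate matter:
#'
#' \deqn{ADI = \frac{C_i \times (C_{PM10}/1000) \times InhR \times EF
#'   \times ED}{BW \times AT \times 10^6}}
#'
#' where `C_i` is the element concentration in the dust (mg/kg),
#' `C_PM10` the exposure-point PM10 concentration (ug/m3; the /1000 converts
#' to mg of dust per m3), and the 10^6 converts mg of dust to kg of dust.
#' The averaging time `AT` is the profile's non-carcinogenic value for
#' `kind = "nc"` and the carcinogenic (lifetime) value for `kind = "ca"`.
#' ADI is exactly linear in both `c_i` and `c_pm10`.
#'
#' @param c_i Element concentration(s) in dust, mg/kg; vectorized.
#' @param c_pm10 Exposure-point PM10 concentration, ug/m3 (a number or an
#'   `"epc"` object).
#' @param profile One-row exposure profile (see [get_profile()]).
#' @param kind `"nc"` (non-carcinogenic) or `"ca"` (carcinogenic); selects
#'   the averaging time.
#' @return ADI in mg/kg-day (numeric, same length as `c_i`).
#' @export
#' @examples
#' adult <- get_profile(load_exposure_profiles(), "adult")
#' average_daily_intake(100, 100, adult, kind = "ca")
average_daily_intake <- function(c_i, c_pm10, profile, kind = c("nc", "ca")) {
  kind <- match.arg(kind)
  if (inherits(c_pm10, "epc")) c_pm10 <- c_pm10$value
  if (any(c_i < 0)) stop("negative element concentration")
  if (c_pm10 < 0) stop("negative PM10 concentration")
  at <- if (kind == "nc") profile$at_nc else profile$at_ca
  c_i * (c_pm10 / 1000) * profile$inhr * profile$ef * profile$ed /
    (profile$bw * at * 1e6)
}
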