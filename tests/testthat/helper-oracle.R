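# Independent plain-arithmetic oracles for the exposure/risk equations,
# written directly from the formulas and kept free of package code.

oracle_adi <- function(c_i, c_pm10, inhr, ef, ed, bw, at) {
  c_i * (c_pm10 / 1000) * inhr * ef * ed / (bw * at * 1e6)
}

oracle_rfd <- function(rfc, inhr, bw) rfc * inhr / bw

oracle_hq <- function(adi, rfd) adi / rfd

oracle_cr <- function(adi, iur, bw, inhr) adi * iur * 1e3 * bw / inhr

# Simplified closed form of the cancer risk in receptor mode, where BW and
# InhR cancel between the intake and risk equations.
oracle_cr_simplified <- function(c_i, c_pm10, ef, ed, iur, at_ca) {
  c_i * c_pm10 * ef * ed * iur / (at_ca * 1e6)
}

# Tiny composition builder for pipeline tests.
make_composition <- function(samples = c("S1", "S2"),
                             elements = c("Cr", "As", "Ni", "Mn"),
                             conc = NULL) {
  grid <- expand.grid(sample = samples, element = elements,
                      stringsAsFactors = FALSE)
  if (is.null(conc)) conc <- seq(10, by = 10, length.out = nrow(grid))
  data.frame(sample = grid$sample, city = "X", element = grid$element,
             concentration = conc, below_lod = FALSE,
             stringsAsFactors = FALSE)
}

# Fixed three-day PM series usable wherever the EPC value is irrelevant.
make_pm <- function(pm10 = c(80, 120, 100), pm25 = pm10 * 0.6) {
  data.frame(date = as.Date("2021-11-01") + seq_along(pm10) - 1,
             pm25 = pm25, pm10 = pm10)
}
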