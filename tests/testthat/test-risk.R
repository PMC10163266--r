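profiles <- load_exposure_profiles()
adult <- get_profile(profiles, "adult")
child <- get_profile(profiles, "child")

test_that("reference dose matches hand evaluations in both modes", {
  expect_equal(reference_dose(0.1, adult), 0.01875)
  expect_equal(reference_dose(0.1, child), 0.1 * 12.5 / 15)
  expect_equal(reference_dose(0.1, child), 0.08333, tolerance = 1e-4)
  # fixed mode applies the adult factor to every receptor
  expect_equal(reference_dose(0.1, child, rfd_mode = "fixed",
                              adult_profile = adult), 0.01875)
  expect_equal(reference_dose(0, adult), 0)
  expect_error(reference_dose(-0.1, adult), "negative")
})

test_that("hazard quotient and index follow the defining arithmetic", {
  adi <- average_daily_intake(100, 100, adult, "nc")
  hq <- hazard_quotient(adi, reference_dose(0.1, adult))
  expect_equal(hq, 9.59e-5, tolerance = 1e-3)
  expect_equal(hazard_quotient(0, 0.5), 0)
  expect_error(hazard_quotient(adi, 0), "RfD")

  expect_equal(hazard_index(c(0.5, 0.69)), 1.19)
  expect_equal(hazard_index(0.71), 0.71)
  set.seed(5)
  hqs <- stats::runif(20)
  expect_equal(hazard_index(hqs), hazard_index(sample(hqs)))
  expect_warning(hi0 <- hazard_index(numeric(0)), "no hazard")
  expect_equal(hi0, 0)
  expect_error(hazard_index(c(0.2, -0.1)), "negative")
})

test_that("cancer risk matches the composed and simplified forms", {
  adi <- average_daily_intake(100, 100, adult, "ca")
  cr <- cancer_risk(adi, 0.01, adult)
  expect_equal(cr, adi * 0.01 * 1000 * 80 / 15)
  expect_equal(cr, 3.562e-5, tolerance = 1e-3)
  # in receptor mode BW and InhR cancel against the intake equation
  expect_equal(cr, oracle_cr_simplified(100, 100, 350, 26, 0.01, 25550),
               tolerance = 1e-12)
  expect_equal(cancer_risk(adi, 0, adult), 0)

  expect_equal(total_cancer_risk(c(1e-5, 2e-5)), 3e-5)
  expect_warning(t0 <- total_cancer_risk(numeric(0)), "no cancer")
  expect_equal(t0, 0)
  set.seed(6)
  crs <- stats::runif(15, 0, 1e-4)
  expect_equal(total_cancer_risk(crs), total_cancer_risk(rev(crs)))
})

test_that("oracle equivalence holds on random inputs to 1e-12", {
  set.seed(101)
  for (i in 1:50) {
    c_i <- stats::runif(1, 0, 2000)
    c_pm <- stats::runif(1, 1, 500)
    rfc <- stats::runif(1, 1e-6, 1)
    iur <- stats::runif(1, 1e-6, 0.1)
    p <- if (i %% 2) adult else child
    adi_nc <- average_daily_intake(c_i, c_pm, p, "nc")
    adi_ca <- average_daily_intake(c_i, c_pm, p, "ca")
    expect_equal(adi_nc, oracle_adi(c_i, c_pm, p$inhr, p$ef, p$ed, p$bw,
                                    p$at_nc), tolerance = 1e-12)
    rfd <- reference_dose(rfc, p)
    expect_equal(rfd, oracle_rfd(rfc, p$inhr, p$bw), tolerance = 1e-12)
    expect_equal(hazard_quotient(adi_nc, rfd), oracle_hq(adi_nc, rfd),
                 tolerance = 1e-12)
    expect_equal(cancer_risk(adi_ca, iur, p),
                 oracle_cr(adi_ca, iur, p$bw, p$inhr), tolerance = 1e-12)
  }
})

test_that("classification bands use the documented boundary conventions", {
  th <- risk_thresholds()
  expect_equal(classify_hazard_index(0.71, th), "no_risk")
  expect_equal(classify_hazard_index(5.28, th), "risk")
  expect_equal(classify_hazard_index(1.0, th), "no_risk")  # strict >
  expect_equal(classify_hazard_index(1.0 + 1e-9, th), "risk")

  expect_equal(classify_cancer_risk(5e-7, th), "acceptable")
  expect_equal(classify_cancer_risk(1e-6, th), "acceptable")  # at or lower
  expect_equal(classify_cancer_risk(2e-6, th), "tolerable")
  expect_equal(classify_cancer_risk(1e-4, th), "tolerable")
  expect_equal(classify_cancer_risk(1.33e-4, th), "unacceptable")
})

test_that("strict mode: HQ receptor-independent, CR free of BW and InhR", {
  set.seed(102)
  for (i in 1:5) {
    comp <- make_composition(conc = stats::runif(8, 1, 500))
    rep <- suppressWarnings(assess_sites(comp, make_pm(), mode = "strict"))
    s <- rep$sites
    for (smp in unique(s$sample)) {
      expect_equal(s$hi[s$sample == smp & s$receptor == "adult"],
                   s$hi[s$sample == smp & s$receptor == "child"])
    }
    # CR equals the simplified closed form per element
    el <- rep$elements
    tox <- load_toxicity_table()
    has <- !is.na(el$cr)
    iur <- tox$iur[match(el$element, tox$element)]
    p <- profiles[match(el$receptor, profiles$receptor), ]
    expect_equal(
      el$cr[has],
      oracle_cr_simplified(el$concentration[has], rep$epc$value,
                           p$ef[has], p$ed[has], iur[has], p$at_ca[has]),
      tolerance = 1e-12
    )
  }
})

test_that("replicate mode reproduces the published child/adult ratios", {
  set.seed(103)
  comp <- make_composition(samples = c("A", "B", "C"),
                           conc = stats::runif(12, 1, 800))
  rep <- suppressWarnings(assess_sites(comp, make_pm(), mode = "replicate"))
  s <- rep$sites
  for (smp in unique(s$sample)) {
    a <- s[s$sample == smp & s$receptor == "adult", ]
    c_ <- s[s$sample == smp & s$receptor == "child", ]
    expect_equal(c_$hi / a$hi, 40 / 9, tolerance = 1e-10)
    expect_equal(c_$cr_total / a$cr_total,
                 (12.5 * 6 * 80 * 25550) / (15 * 26 * 15 * 2190),
                 tolerance = 1e-10)
  }
})

test_that("report invariants: HI and total CR are exact sums, all >= 0", {
  camp <- generate_campaign(generator_config(seed = 3))
  rep <- suppressWarnings(assess_sites(camp$composition, camp$pm))
  s <- rep$sites
  el <- rep$elements
  expect_true(all(s$hi >= 0) && all(s$cr_total >= 0))
  expect_true(all(el$hq >= 0, na.rm = TRUE))
  expect_true(all(el$cr >= 0, na.rm = TRUE))
  for (i in seq_len(nrow(s))) {
    sub <- el[el$sample == s$sample[i] & el$receptor == s$receptor[i], ]
    expect_equal(s$hi[i], sum(sub$hq, na.rm = TRUE))
    expect_equal(s$cr_total[i], sum(sub$cr, na.rm = TRUE))
  }
})

test_that("risks scale linearly with the PM10 exposure concentration", {
  comp <- make_composition()
  r1 <- suppressWarnings(assess_sites(comp, 100))
  r2 <- suppressWarnings(assess_sites(comp, 200))
  expect_equal(r2$sites$hi, 2 * r1$sites$hi)
  expect_equal(r2$sites$cr_total, 2 * r1$sites$cr_total)
})

test_that("pipeline guards: element overlap and skipped-element accounting", {
  comp <- make_composition(elements = c("Xx", "Yy"))
  expect_error(suppressWarnings(assess_sites(comp, make_pm())), "no overlap")

  comp <- make_composition(elements = c("Mn", "Zn", "As"))
  expect_warning(rep <- assess_sites(comp, make_pm()), "IUR")
  # Mn and Zn have no IUR: excluded from CR, never silently zeroed
  el <- rep$elements
  expect_true(all(is.na(el$cr[el$element %in% c("Mn", "Zn")])))
  expect_true(all(!is.na(el$cr[el$element == "As"])))
  expect_equal(rep$skipped$n_no_iur, 2)
})

test_that("risk_report methods print, summarize and coerce", {
  comp <- make_composition()
  rep <- suppressWarnings(assess_sites(comp, make_pm()))
  expect_output(print(rep), "mode: strict")
  sm <- summary(rep)
  expect_s3_class(sm, "summary.risk_report")
  expect_output(print(sm), "leading")
  expect_identical(as.data.frame(rep), rep$sites)
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(rep))
})
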