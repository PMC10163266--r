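test_that("generation is deterministic given the seed", {
  cfg <- generator_config(seed = 77)
  expect_identical(generate_composition(cfg), generate_composition(cfg))
  expect_identical(generate_pm_series(cfg), generate_pm_series(cfg))
  cfg2 <- generator_config(seed = 78)
  expect_false(identical(generate_composition(cfg)$concentration,
                         generate_composition(cfg2)$concentration))
})

test_that("GSD of 1 collapses every draw to the geometric mean", {
  els <- data.frame(element = c("Fe", "Ni"), gm = c(30000, 60), gsd = c(1, 1))
  cfg <- generator_config(elements = els, seed = 5)
  comp <- generate_composition(cfg)
  off <- generator_config(seed = 5)$sites$offset
  for (el in els$element) {
    got <- comp$concentration[comp$element == el]
    expect_equal(got, els$gm[els$element == el] * off)
  }
})

test_that("sampled geometric mean recovers the configured value at n = 500", {
  sites <- data.frame(sample = "S", city = "X", offset = 1)
  els <- data.frame(element = "Ni", gm = 100, gsd = 2)
  cfg <- generator_config(elements = els, sites = sites, n_samples = 500,
                          seed = 11)
  comp <- generate_composition(cfg)
  expect_equal(nrow(comp), 500)
  log_draws <- log(comp$concentration)
  # 3 standard errors of the log-mean: 3 * log(gsd) / sqrt(n)
  se3 <- 3 * log(2) / sqrt(500)
  expect_lt(abs(mean(log_draws) - log(100)), se3)
  expect_lt(abs(stats::sd(log_draws) - log(2)), 3 * log(2) / sqrt(2 * 499))
})

test_that("per-element streams are independent of the panel composition", {
  sites <- data.frame(sample = c("A", "B"), city = "X", offset = c(1, 2))
  base <- data.frame(element = c("Ni", "As"), gm = c(60, 8),
                     gsd = c(1.5, 1.6))
  wider <- rbind(base, data.frame(element = "Cd", gm = 0.4, gsd = 1.8))
  c1 <- generate_composition(generator_config(elements = base, sites = sites,
                                              seed = 9))
  c2 <- generate_composition(generator_config(elements = wider, sites = sites,
                                              seed = 9))
  for (el in base$element) {
    expect_identical(c1$concentration[c1$element == el],
                     c2$concentration[c2$element == el])
  }
})

test_that("dust events scale both size fractions by the magnitude", {
  pm_cfg <- list(gm_pm25 = 35, gsd_pm25 = 1.6, gm_pm10 = 50, gsd_pm10 = 1.6,
                 event_prob = 0, event_magnitude = 10, n_days = 120)
  cfg0 <- generator_config(pm = pm_cfg, seed = 13)
  quiet <- generate_pm_series(cfg0)
  expect_equal(sum(attr(quiet, "event_days")), 0)

  pm_cfg$event_prob <- 1
  cfg1 <- generator_config(pm = pm_cfg, seed = 13)
  stormy <- generate_pm_series(cfg1)
  expect_equal(sum(attr(stormy, "event_days")), 120)
  # same seed, so every day is exactly 10x its quiet baseline
  expect_equal(stormy$pm10, quiet$pm10 * 10)
  expect_equal(stormy$pm25, quiet$pm25 * 10)
})

test_that("PM series respects per-day ordering and binomial event counts", {
  cfg <- generator_config(seed = 17)
  pm <- generate_pm_series(cfg)
  expect_equal(nrow(pm), 150)
  expect_true(all(pm$pm25 <= pm$pm10))
  expect_true(all(pm$pm25 >= 0))
  n_events <- sum(attr(pm, "event_days"))
  bounds <- stats::qbinom(c(0.005, 0.995), 150, 0.2)
  expect_gte(n_events, bounds[1])
  expect_lte(n_events, bounds[2])
})

test_that("configuration invariants are enforced", {
  expect_error(generator_config(elements = data.frame(
    element = "Ni", gm = -1, gsd = 1.5)), "geometric means")
  expect_error(generator_config(elements = data.frame(
    element = "Ni", gm = 60, gsd = 0.9)), "deviations")
  expect_error(generator_config(n_samples = 0), "n_samples")
  expect_error(generator_config(pm = list(
    gm_pm25 = 35, gsd_pm25 = 1.6, gm_pm10 = 30, gsd_pm10 = 1.6,
    event_prob = 0.2, event_magnitude = 4, n_days = 150)), "PM10")
  expect_error(generator_config(pm = list(
    gm_pm25 = 35, gsd_pm25 = 1.6, gm_pm10 = 50, gsd_pm10 = 1.6,
    event_prob = 1.2, event_magnitude = 4, n_days = 150)), "event_prob")
})

test_that("YAML configs load with defaults filled in", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "seed: 99",
    "n_samples: 2",
    "pm:",
    "  n_days: 30",
    "  event_prob: 0.5",
    "elements:",
    "  - {element: Ni, gm: 60, gsd: 1.5}",
    "  - {element: As, gm: 8, gsd: 1.6}",
    "sites:",
    "  - {sample: S1, city: Alpha, offset: 1.0}",
    "  - {sample: S2, city: Beta, offset: 1.2}"
  ), tmp)
  cfg <- read_generator_config(tmp)
  expect_equal(cfg$seed, 99L)
  expect_equal(cfg$n_samples, 2L)
  expect_equal(cfg$pm$n_days, 30)
  expect_equal(cfg$pm$event_magnitude, 4)  # default retained
  expect_equal(nrow(cfg$elements), 2)
  camp <- generate_campaign(cfg)
  expect_equal(nrow(camp$composition), 2 * 2 * 2)
  expect_equal(nrow(camp$pm), 30)
  # explicit seed argument overrides the file
  cfg2 <- read_generator_config(tmp, seed = 7)
  expect_equal(cfg2$seed, 7L)
})

test_that("generated campaigns drive the full pipeline monotonically", {
  cfg_lo <- generator_config(seed = 23)
  cfg_hi <- cfg_lo
  cfg_hi$elements$gm <- cfg_hi$elements$gm * 2
  lo <- generate_campaign(cfg_lo)
  hi <- list(composition = generate_composition(cfg_hi), pm = lo$pm)
  r_lo <- suppressWarnings(assess_sites(lo$composition, lo$pm))
  r_hi <- suppressWarnings(assess_sites(hi$composition, hi$pm))
  expect_true(all(is.finite(r_lo$sites$hi)))
  expect_true(all(r_lo$sites$hi >= 0 & r_lo$sites$cr_total >= 0))
  # doubling every geometric mean doubles each draw, hence each HI and CR
  expect_equal(r_hi$sites$hi, 2 * r_lo$sites$hi)
  expect_equal(r_hi$sites$cr_total, 2 * r_lo$sites$cr_total)
})
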