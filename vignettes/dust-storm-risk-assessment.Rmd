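---
title: "Assessing inhalation health risk and endpoint impacts of heavy-metal dust storms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing inhalation health risk and endpoint impacts of heavy-metal dust storms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dustrisk)
```

## The problem

Dust storms over desiccated basins carry crustal particles enriched in
trace metals. People living around such basins inhale these particles, and
the metals they carry — chromium, arsenic, nickel, manganese, cobalt,
cadmium, lead among others — pose both non-carcinogenic and carcinogenic
health risks, as well as ecotoxicological burdens. `dustrisk` implements
the standard US EPA inhalation risk calculus for this setting, an
endpoint-level ("damage"-level) impact characterization of the particle
composition, and a seeded synthetic generator of monitoring campaigns so
that the full pipeline can be developed and tested without field data.

Only the inhalation route is assessed. Dermal and ingestion exposure to
atmospheric particles are outside the model, as is any satellite or
source-apportionment analysis.

## The exposure and risk model

For each trace element \(i\) with concentration \(C_i\) (mg per kg of
dust), the average daily intake through inhalation (mg per kg body weight
per day) is

\[
ADI_{inh,i} \;=\; \frac{C_i \times (C_{PM10}/1000) \times InhR \times EF
\times ED}{BW \times AT \times 10^{6}}
\]

where \(C_{PM10}\) is the exposure-point concentration of PM10 in air
(µg/m³), \(InhR\) the inhalation rate (m³/day), \(EF\) the exposure
frequency (days/year), \(ED\) the exposure duration (years), \(BW\) the
body weight (kg) and \(AT\) the averaging time (days). The division by
1000 converts µg of dust per m³ to mg, and the \(10^6\) converts mg of
dust to kg of dust, so the two concentration bases compose correctly.

Non-carcinogenic risk uses the hazard quotient and hazard index

\[
HQ_i = \frac{ADI_{inh,i}}{RfD_{inh,i}}, \qquad
RfD_{inh,i} = RfC_i \frac{InhR}{BW}, \qquad
HI = \sum_i HQ_i
\]

and carcinogenic risk the inhalation unit risk \(IUR\) ((µg/m³)⁻¹):

\[
CR_{inh,i} = ADI_{inh,i} \times IUR \times 10^{3} \times \frac{BW}{InhR},
\qquad CR = \sum_i CR_{inh,i}.
\]

Decision conventions, all configurable through `risk_thresholds()`:
HI strictly greater than 1 flags non-carcinogenic risk (1.0 exactly does
not); CR at or below 10⁻⁶ is acceptable, above 10⁻⁶ up to and including
10⁻⁴ is within the regulatory tolerable band, and beyond 10⁻⁴
unacceptable. The boundary conventions are asserted in the test suite so
that counts of exceeding sites are unambiguous.

### Receptors

Two receptor classes are bundled (`load_exposure_profiles()`): an adult
(InhR 15 m³/day, EF 350 days/yr, ED 26 yr, BW 80 kg, AT 9490 days
non-carcinogenic / 25550 days carcinogenic) and a 2–6 year old child
(InhR 12.5, ED 6, BW 15, AT 2190 / 25550). Note that the
non-carcinogenic averaging time equals \(ED \times 365\) for both — an
algebraic fact with visible consequences below.

### The exposure-point concentration

The intake equation needs one "reasonable maximum exposure" PM10 value
for the campaign. The estimator is deliberately pluggable
(`exposure_point_concentration()`): the default is the one-sided
Student-t 95% upper confidence limit of the arithmetic mean,
\(\bar{x} + t_{0.95,n-1}\, s/\sqrt{n}\), which is the baseline EPA
recommendation for approximately normal data and the simplest defensible
choice when the underlying daily series is available; `mean` and `max`
are provided as alternatives, and the method used is recorded in every
report. With zero variance the UCL collapses to the mean, and by
construction it is never below the mean. One EPC is computed per campaign
and shared across all sites, mirroring the single-station design of
typical campaigns.

### Chromium speciation

Toxicity differs sharply between hexavalent and trivalent chromium, so
total chromium is speciated before any risk arithmetic. The default ratio
Cr(VI):Cr(III) = 1:6 makes the hexavalent species one seventh of measured
total chromium, a value representative of crustal dust; the ratio is an
argument wherever speciation occurs. `cr3` is defined as the complement
of `cr6`, so mass is conserved to the last floating-point digit. The
bundled toxicity table carries the two species only — total chromium
deliberately has no reference values, so an unspeciated table cannot be
assessed silently.

## Two computation modes

`assess_sites()` exposes a `mode` argument with two settings, and this is
the one place where the package takes a documented position on an
ambiguity in published site tables of this kind.

* **strict** applies the equations above literally, with each receptor's
  own parameters everywhere. Two algebraic consequences follow, both
  property-tested: because \(AT_{nc} = ED \times 365\) for each receptor,
  BW, InhR and ED all cancel between the intake and reference-dose
  equations and the hazard quotient is *receptor-independent*; and BW and
  InhR cancel between the intake and cancer-risk equations, leaving
  \(CR = C_i\, C_{PM10}\, EF\, ED\, IUR / (AT_{ca}\, 10^6)\), so the
  child's cancer risk is \(6/26\) of the adult's.

* **replicate** reproduces the internal conventions evident in published
  site tables for this assessment style, which consistently show child
  HI ≈ 4.44× adult and child CR ≈ 11.97× adult — ratios the literal
  equations cannot produce. Those ratios follow exactly if (a) a single
  adult-derived reference dose is used for both receptors, (b) the adult
  BW/InhR factor is applied in the cancer-risk equation for both
  receptors, and (c) the child's carcinogenic averaging time is set to
  its non-carcinogenic value (\(6 \times 365 = 2190\) days) while the
  adult keeps the 70-year lifetime. Then
  \(HI_{child}/HI_{adult} = (12.5/15)(80/15) = 40/9 = 4.4\overline{4}\)
  and \(CR_{child}/CR_{adult} =
  (12.5/15)(6/26)(80/15)(25550/2190) = 11.9658\).

Neither mode is labelled "correct": `replicate` documents an inference
about computational conventions, not a claim about intent, and the mode
used is echoed in every report. The bundled published 11-site campaign
table (`published_site_risk()`) satisfies the replicate ratios at every
site, which is the fixture check in the test suite.

```{r modes}
camp <- generate_campaign(generator_config(seed = 1))
rep <- suppressWarnings(assess_sites(camp$composition, camp$pm,
                                     mode = "replicate"))
s <- rep$sites
unique(round(s$hi[s$receptor == "child"] / s$hi[s$receptor == "adult"], 6))
```

## Handling incomplete reference data

Elements without a reference concentration are omitted from the hazard
index, and elements without a unit risk from the cancer risk — with a
counted warning each time, never a silent zero, since silent zeros would
bias HI and CR downward invisibly. Elements absent from the toxicity
table altogether are reported once per assessment. The bundled toxicity
table is a pinned, dated snapshot with a provenance column (screening
reference values are living resources and change between revisions);
values route-extrapolated from oral reference doses are marked as
demonstration entries. Users performing a real assessment should supply
their own current table via `load_toxicity_table(path)`.

Below-detection-limit concentrations are resolved at ingest
(`read_composition_table()`), defaulting to LOD/2 — the common
risk-assessment convention, chosen here as the default because halfway
imputation neither discards the element nor credits it with a full
detection; `zero` and `keep` policies are available, and the flag is
retained so censored values remain identifiable downstream.

## Endpoint characterization

`characterize_impacts()` multiplies each element's mass in a fixed basis
mass of particles (default 1 g; \(C_i \times m \times 10^{-9}\) kg of
element) by per-element endpoint characterization factors in five
categories — human carcinogenic toxicity and human non-carcinogenic
toxicity (DALY/kg), and freshwater, marine and terrestrial ecotoxicity
(species.yr/kg) — and sums within category. The two endpoint totals are
exact sums: human health over the two DALY categories, ecosystems over
the three species.yr categories. In published per-gram tables for crustal
dust the ecological total prints identically to the terrestrial value
because freshwater and marine scores are roughly three orders of
magnitude smaller; the implementation always sums all three, and display
rounding reproduces the printed behaviour (a fixture test verifies the
printed human-health totals are additive to within one unit of the last
displayed digit at all 11 published sites).

Characterization factors are input data. Authoritative endpoint factor
tables are external licensed artifacts, so the bundled set
(`characterization_factors_synthetic.csv`) is synthetic: its values are
order-of-magnitude plausible for the dominant contributors but carry no
authority, and absolute impact scores computed from them should not be
quoted. The emission compartment is fixed to air (single-compartment
model), since airborne particles are the only inventory here.

## The synthetic campaign generator

`generator_config()` describes a campaign: per-element log-normal
concentration distributions (geometric mean, geometric standard
deviation) with per-site multiplicative offsets, and a daily PM2.5/PM10
series with a log-normal baseline and dust-event spikes. Log-normality is
the standard model for strictly positive, right-skewed environmental
concentration data. The defaults emulate a five-month, 11-site campaign
around a desiccated playa: 20 elements dominated by crustal majors (Fe,
Ca, Al, K, Mg), trace metals at literature-plausible levels (e.g. Cr 80,
Ni 60, As 8 mg/kg geometric means), PM baselines of 35/50 µg/m³
geometric mean (GSD 1.6) with events on 20% of days multiplying both
fractions by 4 — so campaign means land near 63/91 µg/m³ with maxima of
several hundred, well above the WHO 24-h guidelines of 15 (PM2.5) and
45 (PM10) µg/m³. The two size fractions share the daily meteorological
log-normal driver with additional fine-fraction noise, and PM2.5 ≤ PM10
is enforced day by day.

The seeding contract matters for reproducibility: one root seed derives
an independent stream per element (hashed from the element name), so
adding or removing an element never perturbs the other elements' draws;
the PM block has its own stream. Everything is bit-reproducible given the
configuration.

What the generator does *not* emulate: spatial or temporal
autocorrelation, co-emission correlation structure between elements,
source-apportionment signatures, seasonal trends, or measurement error
models. Passing tests on generated data therefore demonstrate the
*arithmetic and contracts* of the pipeline — linearity, additivity,
cancellation identities, classification boundaries, determinism — not
that real campaign data would yield any particular risk magnitude.
Absolute HI/CR levels on synthetic data also depend on the demonstration
toxicity snapshot and are not comparable to any published campaign.

```{r generator}
cfg <- generator_config(seed = 42)
camp <- generate_campaign(cfg)
summarize_guideline_exceedance(camp$pm)
```

## Numerical choices and degenerate inputs

* HI and total CR are plain exact sums (no compensated summation; with at
  most a few dozen non-negative terms the rounding error is far below
  any decision threshold). Permutation invariance is property-tested.
* The t-UCL requires n ≥ 2 (no dispersion estimate from one day) and
  errors rather than guessing; a zero-variance series returns its mean.
* An empty hazard-quotient or cancer-risk set yields 0 with a warning —
  distinguishable from a computed zero.
* Speciation defines Cr(III) as `total - cr6`, conserving mass to the
  ulp; weights must be strictly positive.
* Classification boundaries: HI uses strict `>`; CR uses `<=` at both
  band edges ("at or lower than" 10⁻⁶; tolerable up to and including
  10⁻⁴).
* Report serialization stores full precision plus a 2-significant-figure
  display column, so round-trips are lossless while printed tables match
  the conventional display style.

## Problem sizes used in the test suite

The default campaign (11 sites x 20 elements x 150 days) runs the whole
pipeline — generation, EPC, speciation, both assessment modes,
characterization, exceedance summary — in a few seconds. Distributional
recovery checks use n = 500 replicate samples of a single element
(geometric mean recovered within 3 standard errors of the log-mean) and
binomial 99% bounds for dust-event counts; oracle-equivalence checks use
100 random parameter draws against independently coded plain-arithmetic
formulas at 10⁻¹² relative tolerance.

## Known limitations

* Inhalation only; no dermal/ingestion routes, no age-integrated lifetime
  weighting across receptor classes, no Monte-Carlo uncertainty
  propagation.
* The bundled toxicity and characterization tables are demonstration
  data; real assessments must supply current, authoritative tables.
* The UCL estimator family is limited to the Student-t UCL, mean and max;
  heavier-tailed UCL variants (e.g. Chebyshev or bootstrap) are not
  implemented.
* One exposure-point concentration is shared across sites; campaigns with
  per-site PM stations would need one assessment per station.
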