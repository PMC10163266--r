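# Example configuration for the synthetic campaign generator.
# Any key may be omitted; defaults are the bundled Jazmurian-like campaign
# (11 sites, 20 crustal-dominated elements, 150 days of PM observations).
seed: 1
n_samples: 1
pm:
  gm_pm25: 35        # log-normal baseline geometric mean, ug/m3
  gsd_pm25: 1.6
  gm_pm10: 50
  gsd_pm10: 1.6
  event_prob: 0.2    # dust-event probability per day
  event_magnitude: 4 # multiplier applied to both fractions on event days
  n_days: 150
elements:
  - {element: Fe, gm: 30000, gsd: 1.2}   # gm in mg/kg dust
  - {element: Mn, gm: 600, gsd: 1.4}
  - {element: Cr, gm: 80, gsd: 1.5}
  - {element: Ni, gm: 60, gsd: 1.5}
  - {element: As, gm: 8, gsd: 1.6}
sites:
  - {sample: D1, city: Jiroft, offset: 1.1}
  - {sample: D8, city: Kahnooj, offset: 0.8}
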