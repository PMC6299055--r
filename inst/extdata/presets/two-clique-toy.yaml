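# Two small, well separated clusters; quick structural checks.
clusters: {A: 8, B: 8}
within_propensity: 0.3
between_propensity: 0.01
grouping_concentration: 0.9
n_years: 3
survey_days_per_year: 20
presence:
  A: [0.5, 0.5, 0.5]
  B: [0.5, 0.5, 0.5]
core_prob:
  A: [0.5, 0.5, 0.5]
  B: [0.5, 0.5, 0.5]
transients_per_year: 0
n_calves: 0
trawler_interact: {A: 0.2, B: 0.05}
seed: 1
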