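# One undifferentiated cluster, uniform diel schedule, random grouping:
# association structure is off, so every dyad has the same true
# association probability. Used for calibration (type-I error) checks.
clusters: {A: 38}
within_propensity: 0.3
between_propensity: 0.0
grouping_concentration: 0.0
n_years: 9
survey_days_per_year: 14
presence:
  A: [0.35, 0.35, 0.35]
core_prob:
  A: [0.5, 0.5, 0.5]
transients_per_year: 0
n_calves: 0
trawler_interact: {A: 0.05}
seed: 1
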