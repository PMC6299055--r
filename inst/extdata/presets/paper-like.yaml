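# Default three-cluster resident society: 19/13/6 members, 9 survey years,
# morning/evening diel partitioning of the core area, transients, calves,
# trawler interactions concentrated in cluster A. All values are the
# society_config() defaults; listed here for visibility.
clusters: {A: 19, B: 13, C: 6}
within_propensity: 0.3
between_propensity: 0.01
grouping_concentration: 0.7
n_years: 9
survey_days_per_year: 14
seed: 1
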