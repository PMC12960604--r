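# itp_china_2024: published input set for the second-line TPO-RA
# cost-utility model (2024 CNY). Every uncertain parameter carries its
# base-case value, lower/upper values, and PSA distribution family.
efficacy:
  p_response_eltrombopag: {base: 0.5770, low: 0.4616, high: 0.6924, dist: beta}
  or_elt_vs_het: {base: 0.74, low: 0.38, high: 1.43, dist: lognormal}
  or_elt_vs_ava: {base: 0.56, low: 0.29, high: 1.09, dist: lognormal}
  mean_duration_elt: {base: 42.66, low: 34.13, high: 51.19, dist: lognormal}
  p_response_subsequent: {base: 0.7920, low: 0.6336, high: 0.9504, dist: beta}
  mean_duration_subsequent: {base: 46.72, low: 37.38, high: 56.07, dist: lognormal}
  time_to_response: {base: 1.0, low: 1.0, high: 1.0, dist: fixed}
mortality:
  smr_bsc: {base: 4.2, low: 1.7, high: 10.0, dist: lognormal}
  life_table: synthetic
bleeding:
  p_minor_on_treatment: {base: 0.0108, low: 0.0086, high: 0.0130, dist: beta}
  p_minor_bsc: {base: 0.0381, low: 0.0305, high: 0.0457, dist: beta}
  p_severe_bsc: {base: 0.0015, low: 0.0012, high: 0.0018, dist: beta}
  # split of severe bleeds across intracranial / gastrointestinal /
  # other; not reported, equal split assumed
  severe_split: [0.3333333333333333, 0.3333333333333333, 0.3333333333333334]
costs:
  drug_hetrombopag: {base: 6527.92, low: 5222.34, high: 7833.50, dist: gamma}
  drug_eltrombopag: {base: 6365.52, low: 5092.42, high: 7638.62, dist: gamma}
  drug_avatrombopag: {base: 11088.00, low: 8870.40, high: 13305.60, dist: gamma}
  rituximab: {base: 4120.00, low: 3296.00, high: 4944.00, dist: gamma}
  rhtpo: {base: 14026.21, low: 11220.97, high: 16831.45, dist: gamma}
  admin_tpora: {base: 41.04, low: 32.83, high: 49.25, dist: gamma}
  admin_subsequent: {base: 1094.40, low: 875.52, high: 1313.28, dist: gamma}
  management: {base: 463.00, low: 370.40, high: 555.60, dist: gamma}
  minor_bleed: {base: 132.62, low: 106.10, high: 159.15, dist: gamma}
  ich: {base: 21017.80, low: 16814.24, high: 25221.36, dist: gamma}
  gi_bleed: {base: 8398.50, low: 6718.80, high: 10078.20, dist: gamma}
  other_severe: {base: 8398.50, low: 6718.80, high: 10078.20, dist: gamma}
  terminal: {base: 37442.00, low: 29954.00, high: 44930.00, dist: gamma}
utilities:
  u_response_no_bleed: {base: 0.863, low: 0.457, high: 1.000, dist: beta}
  u_response_minor: {base: 0.734, low: 0.295, high: 0.986, dist: beta}
  u_bsc_no_bleed: {base: 0.841, low: 0.320, high: 0.999, dist: beta}
  u_bsc_minor: {base: 0.732, low: 0.294, high: 0.985, dist: beta}
  u_ich: {base: 0.038, low: 0.030, high: 0.046, dist: beta}
  u_gi: {base: 0.540, low: 0.432, high: 0.648, dist: beta}
  u_other_severe: {base: 0.540, low: 0.432, high: 0.648, dist: beta}
settings:
  annual_discount: 0.05
  cycle_days: 28
  wtp: 287391
  start_age: 45
  max_age: 100
  psa_iterations: 5000
  seed: 20240101
  apply_or_to_duration: false
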