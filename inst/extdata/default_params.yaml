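# Default model inputs: per-cycle (3-month) probabilities, utilities and costs
# for the four treatment arms, NYHA transition matrix, age-banded non-CV
# mortality, and run settings. All costs in USD, probabilities as decimals.
probabilities:
  cv_death:
    dapagliflozin: 0.01650
    control1: 0.01994
    empagliflozin: 0.01956
    control2: 0.02120
  hf_hospitalization:
    dapagliflozin: 0.01668
    control1: 0.02344
    empagliflozin: 0.02619
    control2: 0.03719
  hf_readmission: 0.1189
noncv_mortality:
  - {age_low: 65, age_high: 69, prob: 0.002430}
  - {age_low: 70, age_high: 74, prob: 0.003042}
  - {age_low: 75, age_high: 79, prob: 0.004185}
nyha_matrix:
  NYHA1: [0.977, 0.019, 0.004, 0.0]
  NYHA2: [0.008, 0.981, 0.010, 0.001]
  NYHA3: [0.0, 0.034, 0.960, 0.006]
  NYHA4: [0.0, 0.0, 0.055, 0.945]
utilities:
  per_cycle:
    NYHA1: 0.2035
    NYHA2: 0.18
    NYHA3: 0.1475
    NYHA4: 0.127
  event_disutility: -0.1
costs:
  standard: 118.95
  dapagliflozin: 60.93
  empagliflozin: 59.25
  hospitalization: 1785.36
settings:
  start_age: 66
  cycle_length: 0.25
  horizon: 10
  annual_discount: 0.05
  wtp_per_qaly: 11008.07
  gdp_per_capita: 11008.07
  initial_distribution: [0.0, 0.713, 0.28, 0.007]
  half_cycle_correction: true
  discount_convention: mid_cycle
  noncv_mortality_is_annual: false
  dirichlet_concentration: 1000
  sample_nyha: true
# Uncertain-parameter ranges and sampling families. Ranges are treated as 95%
# central intervals when fitting Beta/Gamma distributions; "fixed" entries are
# varied one-way only, never sampled.
ranges:
  - {path: cv_death.dapagliflozin, low: 0.01485, high: 0.01815, distribution: beta}
  - {path: cv_death.control1, low: 0.01795, high: 0.02193, distribution: beta}
  - {path: cv_death.empagliflozin, low: 0.01760, high: 0.02152, distribution: beta}
  - {path: cv_death.control2, low: 0.01908, high: 0.02332, distribution: beta}
  - {path: hf_hospitalization.dapagliflozin, low: 0.0150, high: 0.01835, distribution: beta}
  - {path: hf_hospitalization.control1, low: 0.02110, high: 0.02578, distribution: beta}
  - {path: hf_hospitalization.empagliflozin, low: 0.02357, high: 0.02881, distribution: beta}
  - {path: hf_hospitalization.control2, low: 0.03347, high: 0.04091, distribution: beta}
  - {path: hf_readmission, low: 0.10701, high: 0.13079, distribution: beta}
  - {path: utility.NYHA1, low: 0.19525, high: 0.2125, distribution: beta}
  - {path: utility.NYHA2, low: 0.17325, high: 0.18725, distribution: beta}
  - {path: utility.NYHA3, low: 0.13775, high: 0.15725, distribution: beta}
  - {path: utility.NYHA4, low: 0.103, high: 0.15125, distribution: beta}
  - {path: event_disutility, low: -0.13, high: -0.08, distribution: beta}
  - {path: cost.standard, low: 118.95, high: 556.21, distribution: gamma}
  - {path: cost.dapagliflozin, low: 48.74, high: 73.12, distribution: gamma}
  - {path: cost.empagliflozin, low: 47.40, high: 71.10, distribution: gamma}
  - {path: cost.hospitalization, low: 964.07, high: 3209.47, distribution: gamma}
  - {path: discount, low: 0.0, high: 0.08, distribution: fixed}
  - {path: nyha.NYHA1, distribution: dirichlet_row}
  - {path: nyha.NYHA2, distribution: dirichlet_row}
  - {path: nyha.NYHA3, distribution: dirichlet_row}
  - {path: nyha.NYHA4, distribution: dirichlet_row}
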