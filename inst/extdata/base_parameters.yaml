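meta:
  description: >
    Base-case parameter registry for the Cambodia diabetes / Health Equity
    Fund microsimulation. Point values are the base case; distribution specs
    (lognormal for costs, beta for probabilities, gamma for income) are used
    only by the probabilistic sensitivity analysis.
  currency: USD (2019)
  units: >
    Costs are per instance (per visit, per inpatient day, per use of
    transport) unless the key says annual; disease parameters are annual
    probabilities. Lognormal specs are (meanlog, sdlog). Distribution specs
    for per-day drug costs are on the annualized (x365) scale. Beta specs are
    (alpha, beta); the gamma income spec is (shape, scale).
  sources: >
    Published national costing studies (2014-2018), household surveys
    (DHS 2014, CSES 2017), WHO Global Health Observatory, Global Burden of
    Disease 2017, and UKPDS trial relative risks, as compiled by the
    published economic evaluation this registry mirrors.
costs:
  diagnostics: {point: 1.10, family: lognormal, p1: -0.232, p2: 0.809}
  laboratory: {point: 1.41, family: lognormal, p1: -0.024, p2: 0.857}
  oad_annual: {point: 27.86, family: lognormal, p1: 3.245, p2: 0.406}
  insulin_annual: {point: 125.80, family: lognormal, p1: 4.816, p2: 0.195}
  outpatient_visit:
    hc: {point: 4.15, family: lognormal, p1: 1.299, p2: 0.496}
    cpa1: {point: 10.32, family: lognormal, p1: 2.298, p2: 0.268}
    cpa2: {point: 6.28, family: lognormal, p1: 1.754, p2: 0.408}
    cpa3: {point: 44.40, family: lognormal, p1: 3.791, p2: 0.059}
  inpatient_day:
    hc: {point: 4.77, family: lognormal, p1: 1.479, p2: 0.408}
    cpa1: {point: 59.73, family: lognormal, p1: 4.083, p2: 0.115}
    cpa2: {point: 29.53, family: lognormal, p1: 3.378, p2: 0.115}
    cpa3: {point: 40.85, family: lognormal, p1: 3.703, p2: 0.115}
  transport_outpatient: {point: 0.92, family: lognormal, p1: -0.138, p2: 0.330}
  transport_inpatient: {point: 11.65, family: lognormal, p1: 2.453, p2: 0.068}
  discount_rate: 0.03
population:
  all_cause_mortality: 0.046
  diabetes_incidence: 0.001
  diabetes_prevalence: 0.062
  diabetes_mortality: 0.030
  income: {point: 5783, family: gamma, p1: 0.5, p2: 11566.32}
  life_expectancy: {male: 67, female: 71}
  sex_ratio_male: 0.5
  age_min: 25
  age_max: 69
  poverty_line_daily: 1.90
  # Synthetic Gompertz-shaped age schedule of background mortality: relative
  # hazard exp(slope * (age - age_min)), rescaled at load time so that the
  # mean over the uniform baseline age range equals all_cause_mortality.
  mortality_gompertz_slope: 0.08
disability:
  uncomplicated: 0.049
  dw_undiagnosed_counts: true
complications:
  nephropathy:
    incidence: 0.0100
    rr_therapy: 0.30
    disability_weight: 0.569
    case_fatality: 0.311
    cost: {point: 6358, family: lognormal, p1: 8.733, p2: 0.219}
    cost_unit: per_year
    cost_setting: outpatient
    acute: false
  retinopathy:
    incidence: 0.0212
    rr_therapy: 0.68
    disability_weight: 0.184
    case_fatality: 0.0
    cost: {point: 330, family: lognormal, p1: 5.792, p2: 0.115}
    cost_unit: per_year
    cost_setting: outpatient
    acute: false
  neuropathy:
    incidence: 0.0466
    rr_therapy: 0.94
    disability_weight: 0.133
    case_fatality: 0.0
    cost: {point: 2.62, family: lognormal, p1: 6.862, p2: 0.029}
    cost_unit: per_day
    cost_setting: outpatient
    acute: false
  angina:
    incidence: 0.0067
    rr_therapy: 0.68
    disability_weight: 0.080
    case_fatality: 0.0
    cost: {point: 7.07, family: lognormal, p1: 7.855, p2: 0.29}
    cost_unit: per_day
    cost_setting: outpatient
    acute: false
  pvd:
    incidence: 0.0085
    rr_therapy: 0.74
    disability_weight: 0.014
    case_fatality: 0.002
    cost: {point: 7.07, family: lognormal, p1: 7.855, p2: 0.29}
    cost_unit: per_day
    cost_setting: outpatient
    acute: false
  mi:
    incidence: 0.174
    rr_therapy: 0.39
    disability_weight: 0.432
    case_fatality: 0.707
    cost: {point: 7.07, family: lognormal, p1: 7.855, p2: 0.29}
    cost_unit: per_day
    cost_setting: inpatient
    acute: true
  stroke:
    incidence: 0.0053
    rr_therapy: 0.59
    disability_weight: 0.588
    case_fatality: 0.693
    cost: {point: 2.62, family: lognormal, p1: 6.862, p2: 0.029}
    cost_unit: per_day
    cost_setting: inpatient
    acute: true
  heart_failure:
    incidence: 0.0033
    rr_therapy: 0.68
    disability_weight: 0.179
    # No published value; conservative default matching the other
    # complications assumed non-fatal. Overridable here.
    case_fatality: 0.0
    cost: {point: 7.07, family: lognormal, p1: 7.855, p2: 0.29}
    cost_unit: per_day
    cost_setting: inpatient
    acute: false
care:
  p_diagnosis: {point: 0.370, family: beta, p1: 8.241, p2: 14.057}
  p_outpatient_nonhef: {point: 0.117, family: beta, p1: 0.916, p2: 4.412}
  p_outpatient_hef: {point: 0.172, family: beta, p1: 0.420, p2: 3.171}
  p_inpatient: {point: 0.015, family: beta, p1: 8.850, p2: 581.150}
  provider_shares:
    hc: {point: 0.114, family: beta, p1: 9.755, p2: 107.796}
    cpa1: {point: 0.025, family: beta, p1: 10.943, p2: 574.050}
    cpa2: {point: 0.030, family: beta, p1: 11.862, p2: 557.843}
    cpa3: {point: 0.042, family: beta, p1: 7.304, p2: 190.218}
  p_oad: 0.224
  p_insulin: 0.017
  p_combo: 0.07
  p_oad_to_insulin: 0.04
  p_adherence: 0.125
  rr_diet: 0.90
  los_days: 5
hef:
  eligibility_percentile: 0.20
  enrollment: 0.75
  subsidy: 1.00
  utilization: 1.00
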