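# Base-case model inputs for the polypill cost-utility model.
# Units: costs USD, probabilities per year, utilities on [0,1], ratios unitless.
# Each uncertain entry is {mean, sd, dist}; ranged entries give both age
# endpoints and are interpolated linearly over settings$risk_age_span.

settings:
  discount_cost: 0.058        # annual discount rate applied to costs
  discount_qaly: 0.03         # annual discount rate applied to QALYs
  wtp: 21768                  # willingness-to-pay threshold, USD/QALY (3x GDP per capita, 2020)
  cohort_size: 10000          # reporting multiplier only; results are per person
  start_age: 35
  max_age: 100
  risk_age_span: [35, 85]     # span over which ranged risks interpolate (clamped beyond)
  cycle_length: 1             # years
  half_cycle_correction: true
  cost_model: calibrated      # per_tablet_daily | per_pack_monthly | calibrated
  drug_cost_factor: 0.02381   # 1/42: printed pack prices read as thousand-rial figures at 42,000 rial/USD
  polypill_variant: V         # V (valsartan-based) or E (enalapril-based)
  lognormal_mean_is: arithmetic  # printed RR/HR read as arithmetic mean (or: median)
  sex_mix_male: 0.5           # male fraction used to blend sex-specific MI fatality

life_table:
  file: null                  # path to a CSV (age,qx); null -> synthetic Gompertz table
  gompertz:
    le35: 42                  # target further life expectancy at age 35, years
    doubling_years: 8         # mortality-hazard doubling time
    terminal_age: 100

baseline_risks:
  stroke: {mean: 0.005, sd: 0.003, dist: beta}
  hf:     {mean: 0.004, sd: 0.0023, dist: beta}
  mi:
    low:  {mean: 0.011, sd: 0.0091, dist: beta}
    high: {mean: 0.094, sd: 0.087, dist: beta}
  angina:
    low:  {mean: 0.015, sd: 0.012, dist: beta}
    high: {mean: 0.133, sd: 0.113, dist: beta}
  pvd:
    low:  {mean: 0.007, sd: 0.004, dist: beta}
    high: {mean: 0.062, sd: 0.054, dist: beta}

utilities:
  stroke:       {mean: 0.63, sd: 0.56, dist: beta}
  hf:           {mean: 0.68, sd: 0.49, dist: beta}
  acute_mi:     {mean: 0.76, sd: 0.65, dist: beta}
  post_mi:      {mean: 0.88, sd: 0.74, dist: beta}
  acute_angina: {mean: 0.77, sd: 0.65, dist: beta}
  post_angina:  {mean: 0.88, sd: 0.64, dist: beta}
  pvd:          {mean: 0.9,  sd: 0.7,  dist: beta}
  event_free:   {mean: 1, sd: 0, dist: fixed}

state_costs:                  # USD per year in state (acute states: the event year)
  stroke:       {mean: 1215.5,  sd: 1350, dist: gamma}
  hf:           {mean: 419.9,   sd: 351.8, dist: gamma}
  acute_mi:     {mean: 11461.6, sd: 8376, dist: gamma}
  acute_angina: {mean: 370.4,   sd: 228, dist: gamma}
  pvd:          {mean: 261.94,  sd: 183, dist: gamma}

cost_components:              # itemised components behind the averages (USD)
  angina:
    cardiac_stress_test: 9.4
    electrocardiography: 13.6
    angiography: 299.1
    visit: 48.3
  hf:
    medications: 136.7
    inpatient: 128.9
    outpatient: 1.4
    hospitalization: 153.0
  mi:
    direct: 259.7
    aspirin: 1.6
    tissue_plasminogen_activator: 11200.2

drug_prices:                  # USD per pack of 10 tablets, by dose (mg)
  enalapril:
    "5":  {mean: 14.82, sd: 8, dist: gamma}
    "20": {mean: 24.68, sd: 10, dist: gamma}
  aspirin:
    "80":  {mean: 17.14, sd: 12, dist: gamma}
    "81":  {mean: 8.57,  sd: 7, dist: gamma}
    "100": {mean: 19.71, sd: 14, dist: gamma}
  atorvastatin:
    "10": {mean: 14.57, sd: 9, dist: gamma}
    "20": {mean: 21.42, sd: 18, dist: gamma}
    "40": {mean: 28.28, sd: 20, dist: gamma}
  hydrochlorothiazide:
    "25": {mean: 12.42, sd: 8, dist: gamma}
    "50": {mean: 6.77,  sd: 5, dist: gamma}
  polypill_e:
    "1": {mean: 50.71, sd: 43, dist: gamma}
  polypill_v:
    "1": {mean: 42.85, sd: 29, dist: gamma}

doses:                        # dose selected per arm (key into drug_prices)
  atorvastatin: "20"
  hydrochlorothiazide: "25"   # 12.5 mg given as half a 25 mg tablet
  aspirin: "81"
  enalapril: "20"
dose_fraction:                # fraction of a tablet per daily dose
  hydrochlorothiazide: 0.5

effects:                      # relative effects on annual event risk (RR or HR)
  atorvastatin:
    stroke: {mean: 0.80, sd: 0.6,  dist: lognormal, kind: RR}
    mi:     {mean: 0.72, sd: 0.53, dist: lognormal, kind: RR}
    hf:     {mean: 0.72, sd: 0.53, dist: lognormal, kind: RR}
    angina: {mean: 0.72, sd: 0.53, dist: lognormal, kind: RR}
    pvd:    {mean: 0.85, sd: 0.41, dist: lognormal, kind: RR}
  enalapril:
    stroke: {mean: 0.77, sd: 0.34, dist: lognormal, kind: RR}
    mi:     {mean: 0.72, sd: 0.45, dist: lognormal, kind: RR}
    angina: {mean: 0.74, sd: 0.48, dist: lognormal, kind: RR}
    hf:     {mean: 0.79, sd: 0.51, dist: lognormal, kind: HR}
  aspirin:
    hf:     {mean: 0.71, sd: 0.61, dist: lognormal, kind: RR}
    stroke: {mean: 0.76, sd: 0.67, dist: lognormal, kind: RR}
    mi:     {mean: 1.01, sd: 0.97, dist: lognormal, kind: RR}
    angina: {mean: 1,    sd: 1,    dist: lognormal, kind: RR}
    pvd:    {mean: 0.82, sd: 0.75, dist: lognormal, kind: RR}
  hydrochlorothiazide:
    mi:     {mean: 0.34, sd: 0.23, dist: lognormal, kind: HR}
    stroke: {mean: 0.73, sd: 0.64, dist: lognormal, kind: HR}
    angina: {mean: 0.71, sd: 0.63, dist: lognormal, kind: HR}
    hf:     {mean: 1.05, sd: 0.94, dist: lognormal, kind: HR}
  polypill:
    stroke: {mean: 0.43, sd: 0.23, dist: lognormal, kind: HR}
    hf:     {mean: 0.83, sd: 0.54, dist: lognormal, kind: HR}
    angina: {mean: 0.77, sd: 0.65, dist: lognormal, kind: HR}
    mi:     {mean: 0.66, sd: 0.53, dist: lognormal, kind: HR}

mortality:
  fatal_stroke: {mean: 0.19, sd: 0.12, dist: beta}
  fatal_hf:     {mean: 0.17, sd: 0.09, dist: beta}
  fatal_mi:
    men:
      low:  {mean: 0.19, sd: 0.14, dist: beta}
      high: {mean: 0.36, sd: 0.29, dist: beta}
    women:
      low:  {mean: 0.23, sd: 0.19, dist: beta}
      high: {mean: 0.40, sd: 0.34, dist: beta}
  smr:                        # multipliers on life-table mortality after an event
    stroke: {mean: 2.72, sd: 1.43, dist: gamma}
    mi:     {mean: 2.68, sd: 1.54, dist: gamma}
    hf:     {mean: 2.17, sd: 1.98, dist: gamma}
    angina: {mean: 2.19, sd: 2,    dist: gamma}
    pvd:    {mean: 2.44, sd: 2.01, dist: gamma}
  disease_specific_death: {mean: 0.015, sd: 0.003, dist: beta}
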