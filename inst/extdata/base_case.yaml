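# Base-case run configuration: 2013 Malaysian Ministry of Health
# perspective, three-state Markov model, one-year cycles.
drugs:
  sevelamer:
    dose_g_per_day: 2.184     # mean daily dose, source trial
    price_rm_per_g: 5.0069    # MOH indicative price
  caco3:
    dose_g_per_day: 2.950
    price_rm_per_g: 0.0871    # public-sector generic, Q3 2013
  binder_continues_on_dialysis: true
dialysis:
  hd_cost_rm_per_session: 259.09
  hd_sessions_per_year: 156   # 3 sessions/week
  capd_cost_rm_per_day: 99.04
  capd_days_per_year: 365
  hd_share: 0.88
  capd_share: 0.12
utilities:
  predialysis: 0.86
  dialysis: 0.8
discount:
  costs: 0.03
  outcomes: 0.03
model:
  horizon_years: 60
  cohort_size: 1000
  half_cycle_correction: false
  background_mortality: false
calibration:
  shape: 1.0                  # exponential hazards
  tolerance_ly: 0.05
  targets:                    # published discounted per-patient totals
    sevelamer: {ly: 6.37, cost_rm: 159901}
    caco3: {ly: 4.25, cost_rm: 77139}
trial:
  n_sevelamer: 107
  n_caco3: 105
  followup_months: 36
thresholds:
  gdp_per_capita_rm: 33132    # Malaysia, 2013 (IMF projection)
  usd_exchange_rate: 3.28     # RM per USD, 31 Dec 2013
psa:
  n_sims: 10000
  cv_doses: 0.1
  cv_costs: 0.1
  se_log_hr: 0.15
  se_utility: 0.05
seed: 20130919
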