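settings:
  cycle_length_months: 1
  horizon_months: 60
  discount_rate_annual: 0.035
  wtp_per_qaly: 20000.0
  half_cycle_correction: yes
  reporting_horizons_months:
  - 12
  - 24
  - 36
  - 60
  daycase_fraction:
    base: 1.0
    low: 0.75
    high: 1.0
    family: beta
    provenance: unspecified
strategies:
  Resonance:
    name: Resonance
    planned_exchange_interval_months: 12
    stent_unit_cost_gbp:
      base: 750.0
      low: 600.0
      high: 900.0
      family: gamma
      provenance: placeholder
    insertion_minutes:
      base: 21.0
      low: 16.800000000000001
      high: 25.199999999999999
      family: gamma
      provenance: published
    replacement_minutes:
      base: 31.0
      low: 24.800000000000001
      high: 37.199999999999996
      family: gamma
      provenance: published
  JJ:
    name: JJ
    planned_exchange_interval_months: 6
    stent_unit_cost_gbp:
      base: 30.0
      low: 30.0
      high: 60.0
      family: gamma
      provenance: placeholder
    insertion_minutes:
      base: 20.600000000000001
      low: 16.48
      high: 24.720000000000002
      family: gamma
      provenance: published
    replacement_minutes:
      base: 30.600000000000001
      low: 24.480000000000004
      high: 36.719999999999999
      family: gamma
      provenance: published
clinical:
  p_death:
    base: 0.0505
    low: 0.0404
    high: 0.0606
    family: beta
    provenance: published
  p_uti_resolve:
    base: 0.909090909090909
    low: 0.818181818181818
    high: 1.0
    family: beta
    provenance: modelling assumption
  by_strategy:
    Resonance:
      p_fail:
        base: 0.1502
        low: 0.1202
        high: 0.1802
        family: beta
        provenance: published
      p_uti:
        base: 0.0205
        low: 0.0018
        high: 0.0547
        family: beta
        provenance: published
    JJ:
      p_fail:
        base: 0.3648
        low: 0.2918
        high: 0.4378
        family: beta
        provenance: published
      p_uti:
        base: 0.0085
        low: 0.0068
        high: 0.0102
        family: beta
        provenance: published
utilities:
  u_patent:
    base: 0.8
    low: 0.64
    high: 0.96
    family: beta
    provenance: placeholder
  u_uti:
    base: 0.7
    low: 0.56
    high: 0.84
    family: beta
    provenance: placeholder
  u_failed:
    base: 0.75
    low: 0.6
    high: 0.9
    family: beta
    provenance: placeholder
costs:
  theatre_per_minute:
    base: 20.0
    low: 16.0
    high: 24.0
    family: gamma
    provenance: placeholder
  surgeon_per_minute:
    base: 2.0
    low: 1.6
    high: 2.4
    family: gamma
    provenance: placeholder
  nurse_band6_per_minute:
    base: 1.0
    low: 0.8
    high: 1.2
    family: gamma
    provenance: placeholder
  nurse_band5_per_minute:
    base: 0.75
    low: 0.6
    high: 0.9
    family: gamma
    provenance: placeholder
  consumables_per_procedure:
    base: 100.0
    low: 80.0
    high: 120.0
    family: gamma
    provenance: placeholder
  bed_stay_per_hour:
    base: 20.0
    low: 16.0
    high: 24.0
    family: gamma
    provenance: placeholder
  overnight_stay:
    base: 400.0
    low: 320.0
    high: 480.0
    family: gamma
    provenance: placeholder
  imaging_per_procedure:
    base: 50.0
    low: 40.0
    high: 60.0
    family: gamma
    provenance: placeholder
  gp_visit:
    base: 40.0
    low: 32.0
    high: 48.0
    family: gamma
    provenance: placeholder
  antibiotic_course:
    base: 10.0
    low: 8.0
    high: 12.0
    family: gamma
    provenance: placeholder
  oncology_outpatient_visit:
    base: 200.0
    low: 160.0
    high: 240.0
    family: gamma
    provenance: placeholder
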