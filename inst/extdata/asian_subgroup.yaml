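schema: mbcmarkov-scenario/1
name: asian_subgroup
settings:
  cycle_days: 21.0
  horizon_years: 5.0
  annual_discount_rate: 0.03
  wtp_per_qaly: 36000.0
  gdp_per_capita: 12000.0
  initial_distribution:
    SD: 1.0
    RE: 0.0
    PD: 0.0
    DE: 0.0
  half_cycle_correction: yes
  rounding_mode: full_precision
strategies:
- id: nc
  name: N+C
  clinical:
    rr: 0.705882352941177
    os_months: 23.800000000000001
    pfs_months: 7.0
    dor_months: 11.1
  utilities:
    stable: 0.74
    remission: 0.85
    relapse: 0.5
    death: 0.0
    extras:
      u_no_recurrence_post_chemo: 0.94
      u_local_recurrence_year1: 0.74
  costs:
    dosing:
    - drug: neratinib
      dose_mg: 240.0
      per_m2: no
      unit_mg: 40.0
      unit_price_usd: 13.460000000000001
      admin_per_day: 1.0
      days_per_cycle: 21.0
    - drug: capecitabine
      dose_mg: 1500.0
      per_m2: yes
      unit_mg: 150.0
      unit_price_usd: 0.6
      admin_per_day: 2.0
      days_per_cycle: 14.0
    ae_profile:
    - event: diarrhea
      incidence: 0.307
      cost_per_event: 4083.630000000000109
    - event: ppe_syndrome
      incidence: 0.12
      cost_per_event: 2316.0
    - event: vomiting
      incidence: 0.05
      cost_per_event: 945.629999999999995
    - event: fatigue
      incidence: 0.037
      cost_per_event: 1158.039999999999964
    - event: anemia
      incidence: 0.024
      cost_per_event: 7350.979999999999563
    other_costs:
      hospitalization: 3200.0
      concomitant_medications: 2176.0
      health_examinations: 4552.0
    bsa_m2: 1.67
    loperamide:
      unit_mg: 2.0
      unit_price_usd: 0.23
      initial_mg: 4.0
      loading_interval_h: 4.0
      loading_days: 3.0
      maintenance_interval_h: 6.0
    other_cost_period: per_year
    drug_states: SD
  sa_ranges:
    inc_anemia:
    - 0.0216
    - 0.0264
    inc_diarrhea:
    - 0.2763
    - 0.3377
    inc_fatigue:
    - 0.0333
    - 0.0407
    inc_ppe_syndrome:
    - 0.108
    - 0.132
    inc_vomiting:
    - 0.045
    - 0.055
    p_pd:
    - 0.027423182864188
    - 0.033517223500674
    p_pp:
    - 0.872576817135812
    - 1.0
    p_rp:
    - 0.04117902066567
    - 0.05032991414693
    p_rr:
    - 0.85882097933433
    - 1.0
    p_sp:
    - 0.164716082662679
    - 0.201319656587719
    p_sr:
    - 0.188695473316652
    - 0.230627800720352
    p_ss:
    - 0.546588444020669
    - 0.668052542691929
- id: lc
  name: L+C
  clinical:
    rr: 0.711229946524064
    os_months: 18.699999999999999
    pfs_months: 5.4
    dor_months: 4.2
  utilities:
    stable: 0.74
    remission: 0.85
    relapse: 0.5
    death: 0.0
    extras:
      u_no_recurrence_post_chemo: 0.94
      u_local_recurrence_year1: 0.74
  costs:
    dosing:
    - drug: lapatinib
      dose_mg: 1250.0
      per_m2: no
      unit_mg: 250.0
      unit_price_usd: 16.120000000000001
      admin_per_day: 1.0
      days_per_cycle: 21.0
    - drug: capecitabine
      dose_mg: 2000.0
      per_m2: yes
      unit_mg: 150.0
      unit_price_usd: 0.6
      admin_per_day: 2.0
      days_per_cycle: 14.0
    ae_profile:
    - event: diarrhea
      incidence: 0.143
      cost_per_event: 4083.630000000000109
    - event: ppe_syndrome
      incidence: 0.138
      cost_per_event: 2316.0
    - event: vomiting
      incidence: 0.024
      cost_per_event: 945.629999999999995
    - event: fatigue
      incidence: 0.04
      cost_per_event: 1158.039999999999964
    - event: anemia
      incidence: 0.044
      cost_per_event: 7350.979999999999563
    other_costs:
      hospitalization: 3200.0
      concomitant_medications: 2176.0
      health_examinations: 4552.0
    bsa_m2: 1.67
    loperamide: ~
    other_cost_period: per_year
    drug_states: SD
  sa_ranges:
    inc_anemia:
    - 0.0396
    - 0.0484
    inc_diarrhea:
    - 0.1287
    - 0.1573
    inc_fatigue:
    - 0.036
    - 0.044
    inc_ppe_syndrome:
    - 0.1242
    - 0.1518
    inc_vomiting:
    - 0.0216
    - 0.0264
    p_pd:
    - 0.034499877372498
    - 0.042166516788609
    p_pp:
    - 0.865500122627502
    - 1.0
    p_rp:
    - 0.104780258327219
    - 0.128064760177712
    p_rr:
    - 0.795219741672781
    - 0.971935239822288
    p_sp:
    - 0.419121033308874
    - 0.512259040710846
    p_sr:
    - 0.189962266439552
    - 0.232176103426119
    p_ss:
    - 0.290916700251574
    - 0.355564855863035
shared_ranges:
  u_stable:
  - 0.592
  - 0.888
  u_remission:
  - 0.68
  - 1.0
  u_relapse:
  - 0.4
  - 0.6
  price_neratinib:
  - 12.114000000000001
  - 14.805999999999999
  price_lapatinib:
  - 14.507999999999999
  - 17.731999999999999
  price_capecitabine:
  - 0.54
  - 0.66
  price_loperamide:
  - 0.207
  - 0.253
  cost_ae_diarrhea:
  - 3675.266999999999825
  - 4491.993000000000393
  cost_ae_ppe_syndrome:
  - 2084.400000000000091
  - 2547.599999999999909
  cost_ae_vomiting:
  - 851.067000000000007
  - 1040.192999999999984
  cost_ae_fatigue:
  - 1042.236000000000104
  - 1273.844000000000051
  cost_ae_anemia:
  - 6615.881999999999607
  - 8086.078000000000429
  cost_hospitalization:
  - 2880.0
  - 3520.0
  cost_concomitant_medications:
  - 1958.400000000000091
  - 2393.599999999999909
  cost_health_examinations:
  - 4096.800000000000182
  - 5007.199999999999818
  discount_rate:
  - 0.027
  - 0.033
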