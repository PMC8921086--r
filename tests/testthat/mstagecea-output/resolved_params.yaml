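start_age: 70
horizon: 5
discount_rate: 0.03
wtp: 100000
p_ct_tp: 0.9225
p_ct_fp: 0.0775
p_mri_detect: 1.0
p_r1: 0.8
p_met_after_resection: 0.38
p_surgery_death: 0.037
p_death_m1: 0.5074
p_death_m0: 0.029
cost_ct: 692
cost_mri: 615
cost_surgery: 42869
cost_m1_therapy: 60000
cost_post_surgery_y1: 36126
cost_post_surgery_later: 1126
cost_m1_after_surgery: 60000
cost_local_recurrence: 30000
u_m1_post_surgery: 0.6
u_m1_no_surgery: 0.65
u_m0_post_surgery_y1: 0.726
u_m0_post_surgery_later: 0.797
u_dead: 0.0
structure:
  accrual: start
  utility_set: low
  r1_split_timing: annual
  r1_mortality: m0
  first_year_reference: global
  m1_mortality_onset: deferred
  met_followup: yes

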