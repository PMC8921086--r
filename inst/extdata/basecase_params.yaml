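# Base-case inputs of the M-staging cost-effectiveness model.
# One entry per published model input; currency is US dollars.

start_age: 70            # expected age at the diagnostic procedure (years)
horizon: 5               # Markov model time horizon (annual cycles)
discount_rate: 0.03      # annual discount rate for costs and QALYs
wtp: 100000              # willingness-to-pay per QALY ($)

# Diagnostic test performance (resectability classification on CE-CT)
p_ct_tp: 0.9225          # probability of correct classification as resectable
p_ct_fp: 0.0775          # false-positive resectability (occult metastases)
p_mri_detect: 1.0        # P(added liver MRI detects the occult metastases)

# Costs, acute (one-time, $)
cost_ct: 692             # CT chest/abdomen/pelvis (Medicare-based)
cost_mri: 615            # MRI abdomen (Medicare-based)
cost_surgery: 42869      # pancreatic resection incl. complications

# Costs, long-term ($/year)
cost_m1_therapy: 60000        # palliative therapy, metastatic, not resected
cost_post_surgery_y1: 36126   # therapy/follow-up, first year after resection
cost_post_surgery_later: 1126 # follow-up, subsequent years
cost_m1_after_surgery: 60000  # therapy after resection with metastasis
cost_local_recurrence: 30000  # therapy with local recurrence / R1

# Utilities (QALY weights)
u_m1_post_surgery: 0.6   # metastatic after surgery
u_m1_no_surgery: 0.65    # metastatic without surgery
u_m0_post_surgery_y1: 0.726    # resected, metastasis-free, first year
u_m0_post_surgery_later: 0.797 # resected, metastasis-free, later years
u_dead: 0.0

# Annual transition probabilities
p_r1: 0.8                     # proportion of R1-resections
p_met_after_resection: 0.38   # metastasis occurrence after resection (/year)
p_surgery_death: 0.037        # perioperative mortality (once, at resection)
p_death_m1: 0.5074            # mortality with metastatic disease (/year)
p_death_m0: 0.029             # mortality without metastatic disease (/year)

# Structural flags (the combination selected by the structure search)
structure:
  accrual: start              # rewards on cycle-start occupancy
  utility_set: low            # M0 post-surgery utility pair 0.726 / 0.797
  r1_split_timing: annual     # 80%/yr hazard into the R1/local state
  r1_mortality: m0            # R1/local state uses the M0 death probability
  first_year_reference: global
  m1_mortality_onset: deferred
  met_followup: true
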