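# Example generative specification for a small synthetic cohort.
# Fields mirror the arguments of chain_spec(); kernels are lists of rows.
n_states: 4
kernel:
  - [0.85, 0.13, 0.015, 0.005]
  - [0.09, 0.80, 0.09, 0.02]
  - [0.01, 0.12, 0.77, 0.10]
  - [0.005, 0.015, 0.12, 0.86]
initial_distribution: [0.21, 0.34, 0.22, 0.23]
death_hazard: [0.0001, 0.0003, 0.001, 0.002]
score_edges: [0, 1, 2, 3]
score_max: 8
gap_probability: 0.004
step_minutes: 30
horizon_minutes: 4320
p_ventilated: 0.82
p_age_0_1: 0.50
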