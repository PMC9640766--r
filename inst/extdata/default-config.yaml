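alpha: 0.001
dt: 20.0
tau: 100.0
N_p_in: 11
N_v_in: 153
N_p: 150
N_v: 100
N_p_out: 3
N_v_out: 1
p_0: 0.2
p_1: 0.1
p_2: 1.0
delta_rec2: 0.01
N_trials: 24
durations:
  initial_fixation: 600.0
  first_stimulus: 400.0
  first_delay: 500.0
  second_stimulus: 200.0
  first_decision: 100.0
  mid_fixation: 300.0
  third_stimulus: 200.0
  second_decision: 100.0
learn_block: 50
test_trials: 800
criterion: 0.98
max_iter: 2000
optimizer: adam
clip: 1.0
advantage_mode: return_to_go
value_target: return_to_go
timeout1_reward: -1.0
fixation_bias: 4.0
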