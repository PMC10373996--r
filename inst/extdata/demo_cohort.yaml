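# Demo cohort configuration: the calibrated default emulating the
# development sample's score marginals (n = 158, mean ~71.6, SD ~18.7).
n_participants: 158
theta_mean: 0.65
theta_sd: 1.3
seed: 42
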