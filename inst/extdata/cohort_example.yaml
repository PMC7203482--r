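# Example generator configuration for read_generator_config().
# Omitted fields fall back to the study-design defaults (3600 s sessions,
# 270 s alarms, 16.36 s mean response time, 8 Hz band power, 5 Hz GSR,
# 12 outcome scales).
n_probands: 6
seed: 42
t7_effect: 0.8
band_baseline: {theta: 40, alpha: 30, beta_low: 20, beta_high: 15, gamma: 10}
slider_load: {interest: 1500, energy: 1200, valence: 1300, focus: 1000, tension: -1100}
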