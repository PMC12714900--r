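# Example run configuration (keys mirror community_params field names)
scenario: linear_regime
params:
  mu_P: 0.5
  c_max: 2.0e-4
sampling:
  analyzed_volume: 0.5
  noise: poisson
estimator:
  alpha: 0.05
  duration: 0.5
comparison:
  iqr_k: 1.5
  reference_log10: 5.6
seed: 0
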