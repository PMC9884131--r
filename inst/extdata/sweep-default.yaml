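# Default beta-sweep experiment: univariate linear data, over-side penalty.
beta_grid: [0, 0.01, 0.1, 1, 10]
direction: over
p: 2
normalization: mean
n_replicates: 20
model: linear
generator:
  n: 500
  d: 1
  coefficients: 2
  intercept: 1
  noise_sd: 0.5
test_grid_size: 200
seed: 1
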