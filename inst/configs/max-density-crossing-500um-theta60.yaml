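# Cluster-scale crossing config: two bundles at 60 degrees, 5-degree
# intra-bundle dispersion, trimmed to the central crossing region.
seed: 1
kind: crossing
bundle:
  L: 500
  H: 500
  density: 0.75
  eta: 5
  gamma: {shape: 0.5, scale: 1.1, trunc: [0.5, 4.0]}
crossing:
  theta: 60
  trim: true
growth:
  resolution: 0.1
  cap_factor: 1.5
  iterations: 10000
erode:
  g_target: 0.7
mesh: {enabled: true, smooth_iters: 10, decim_fraction: 0.25}
metrics: {profile_step: 1.0}
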