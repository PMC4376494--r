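# Full pipeline configuration with the package defaults.
bias:
  max_iterations: 50          # per resolution level
  convergence_threshold: 1.0e-3  # CV of exp(field update) inside the FOV
  fitting_levels: 4           # control-point spacing halves per level
  control_point_spacing: 256  # pixels, coarsest level
  histogram_bins: 200
  sharpening_fwhm: 0.15       # log-intensity units
  wiener_noise: 0.01
enhancement:
  r: 3                        # contrast exponent
  h: 81                       # window width (odd)
  open_radius: 1              # disk radius of the binary opening
  binarize_quantile: 0.85
em:
  init: quantile              # or kmeans
  tol: 1.0e-6
  max_iter: 200
  seed: 1
length_filter:
  min_size: 100               # pixels at 565x584 (DRIVE) scale
  scale_with_area: true
channel: green
save_intermediates: false
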