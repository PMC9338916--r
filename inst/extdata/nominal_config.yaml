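# Nominal Michaelis-Menten run configuration (package defaults made explicit).
parameters:
  ka: 1.0      # /h
  V: 1.0       # L
  Vmax: 0.2    # mg/h
  Km: 0.5      # mg/L
dose_mg: 3.0
sampling_times_h: [0.1, 0.25, 0.5, 0.75, 1, 2, 4, 6, 8, 12, 16, 24, 30]
solver:
  variant: indlin_adaptive   # reference | indlin_fixed | indlin_adaptive
  epsilon: 1.0e-6            # successive-error stopping tolerance
  n_max: 20
  ss: 0.01                   # fixed step size (h), used by indlin_fixed
  alpha: 0.01                # adaptive step scale
  ss_min: 1.0e-4
  ss_max: 1.0
estimation:
  smart_update: true
  theta0: null               # null -> start at `parameters`
  max_fev: 400
sse:
  n_reps: 100
  omega2: 0.1                # lognormal BSV variance per parameter
  sigma: 0.1                 # residual log-scale SD
  seed: 1
output_dir: "."
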