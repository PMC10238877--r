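# Demo run: mildly stenosed carotid twin, reduced-order engine,
# hyperemia sweep at x1.0 / x1.5 / x2.0 of the baseline CCA PSV.
engine: reduced
seed: 1
geometry:
  r_cca: 3.5
  r_ica: 2.5
  r_eca: 2.0
  len_cca: 50
  len_ica: 60
  len_eca: 50
  angle_ica: 25
  angle_eca: 25
  resolution: 1.6
  stenoses:
    - branch: ica
      degree: 47
      center_s: 12
      length: 8
solve:
  v_peak: 100
  outlets:
    mode: calibrate
    target_mean_pressure: 90
    baseline_flow: 600
    rc_time_constant: 1.3
sweep:
  v_peak_factors: [1.0, 1.25, 1.5, 1.75, 2.0]
validation:
  cohort:
    n_free: 7
    n_mild: 24
    n_moderate: 6
    dus_noise_cv: 0.1
    cfd_bias_factor: 1.1
    cfd_noise_cv: 0.1
  offset_mm: 0.4
  margin: 0.3
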