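# Simulator presets matching the reported cohort motion statistics
# (mean SI excursion / mean cycle; 5 Hz sampling).
liver:
  mean_period: 4.6
  period_sd: 0.4
  mean_amp_si: 21.3
  mean_amp_ap: 7.9
  mean_amp_lr: 9.3
  amp_sd_frac: 0.1
  drift_mm_per_min: 0.5
  noise_sd: 0.3
  shape_exponent: 4
  duration: 300
  sample_period: 0.2
lung:
  mean_period: 3.4
  period_sd: 0.4
  mean_amp_si: 16.2
  mean_amp_ap: 4.2
  mean_amp_lr: 2.8
  amp_sd_frac: 0.1
  drift_mm_per_min: 0.5
  noise_sd: 0.3
  shape_exponent: 4
  duration: 300
  sample_period: 0.2
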