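# sniqc pipeline configuration
sort:
  allowed_stations: [SIM1, SIM2, CAM_A]
  series_tokens: [UNIFORMITY, FLOOD, DAILY QC]
  min_counts: 1000000
  matrix_sizes:
    - [256, 256]
    - [128, 128]
    - [64, 64]
alerts:
  lower_threshold: 0.50
  upper_threshold: 0.60
geometry:
  distance_cm: 150
  display_cm: 6.5
  peak_cyc_per_deg: 4
  filter_exponent: 1
roi:
  fraction: 0.9
  size: 64
  step: 16
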