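# Planted-regulon demo: 31 synthetic genes with the five-category ground
# truth, classified from growth-corrected promoter activity.
seed: 1
mode: planted
templates: default
layout:
  n_trenches: 60
  cells_per_trench: 1
  frame_interval: 3
  t_pre: 120
  t_post: 360
noise:
  meas_cv: 0.05
  ou_cv: 0.15
  ou_tau: 30
  cell_cv: 0.4
  length_cv: 0.01
classification:
  alpha: 0.05
  threshold: 2.12
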