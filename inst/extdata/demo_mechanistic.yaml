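# Mechanistic demo: a 100 uM step treatment of two OxyR-regulated
# reporters, one with a high OxyR dissociation constant (pulsatile
# regime) and one with a low one (gradually responding regime).
seed: 1
mode: mechanistic
layout:
  n_trenches: 40
  cells_per_trench: 1
  t_pre: 120
  t_post: 360
protocol:
  type: step
  conc: 100
genes:
  - name: katG_like
    R_basal: 0.5
    K_ind: 5.4
    K_D: 0.18
  - name: ahpC_like
    R_basal: 0.5
    K_ind: 0.3
    K_D: 0.01
classification:
  alpha: 0.05
  threshold: 2.12
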