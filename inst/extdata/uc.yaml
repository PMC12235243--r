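# Umbilical-cord MSC case study: estimated senescence-model constants,
# calibrated growth-rate noise, multilayer-flask process settings and the
# default design-variable grid.
cell_source:
  label: UC
  mu_m: 0.0330
  K_sr: 0.332
  K_50: 49.3
  sd_e: 0.00199
process:
  X_s: 5000.0
  X_m: 64100.0
  S: 1720.0
  n_flask_init: 1
  n_flask_max: 10
  Np_grid: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15]
  th_grid: [2.5, 2.75, 3.0, 3.25, 3.5, 3.75, 4.0, 4.25, 4.5, 4.75, 5.0]
  psene_min: 0.8
  pconf_max: 0.9
  ncell_min: 350000000.0
  M: 10000
  pi: 90.0
  xm_cv: 0.05
  seed: 1
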