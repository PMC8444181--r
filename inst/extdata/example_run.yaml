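# Example run configuration for run_config_from_yaml().
# `synthetic` keys mirror synthetic_config() field names exactly.
synthetic:
  mu_E: 2.0        # mean log10 STAT3 expression (log10 a.u.)
  sigma_E: 0.25    # expression heterogeneity (log10 a.u.)
  gain: 1.0
  K: 20.0          # half-maximal Hy-IL-6 dose (ng/ml)
  h: 1.5           # Hill coefficient
  delta_late: 0.25 # late-phase attenuation of the induced component
  mu_B: 1.0        # log10 mean of additive background (a.u.)
  sigma_B: 0.2
  sigma_eps: 0.05  # multiplicative measurement noise (log10 sd)
  n_cells: 6700    # events per condition-replicate
presets: [wt, dEx3, dEx3_SHP2, wt_U0126]
doses: [0, 1, 5, 10, 25, 75, 150]
times: [early, late]
n_replicates: 3
mi_options:
  min_events: 500
cc_options:
  method: ba
seed: 1
output: out
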