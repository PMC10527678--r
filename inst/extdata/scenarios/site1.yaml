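# Site-1-style scenario: short high-density fed-batch (<= 20 h), glucose-only
# exponential feed starting at 5-7 h, dense off-gas sampling, 37 C.
site: 1
duration_h: 20.0
sampling_interval_h: 0.1
feed_start_h: 6.0
feed_start_range_h: [5.0, 7.0]   # per-run draw window used by campaigns
induction_time_h: 8.0
temperature_label: "37C"
initial:
  x0_g_l: 0.25
  s0_g_l: 20.0
  volume_l: 3.7
feed:
  glucose_rate_start_g_h: 6.0    # feed rate at feed start
  glucose_exp_rate_h: 0.15       # exponential ramp of the feed rate
  glucose_feed_conc_g_l: 500.0
  isoleucine_rate_g_h: 0.0
kinetics:
  mu_max: 0.55          # 1/h
  K_S: 0.05             # g/L
  Y_XS: 0.46            # g biomass / g glucose
  qs_crit: 0.9          # g glucose / g biomass / h, oxidative capacity
  Y_AS: 0.6             # g acetate / g glucose routed through overflow
  qac_max: 0.25         # g acetate / g biomass / h, re-uptake capacity
  K_A: 0.05             # g/L
  Y_XA: 0.4             # g biomass / g acetate
oxygen:
  alpha: 1.0            # g O2 / g biomass
  beta: 0.03            # g O2 / g biomass / h (maintenance)
  k_cX: 5.0             # g h/L, cumulative biomass-time engaging beta
  X_cX: 0.0             # g/L
  rq: 1.0               # respiratory quotient (mol CO2 / mol O2)
  rq_drift: 0.05        # linear relative drift of RQ over the run
solutes: {}             # site 1 tracks acetate only
noise:
  our_rel_sd: 0.02
  cpr_rel_sd: 0.02
  broth_rel_sd: 0.005
  assay_rel_sd: 0.02
  assay_abs_sd_g_l: 0.01
assay:
  n_samples: 17
  first_sample_h: 1.0
broth_density_kg_l: 1.0
seed: 1
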