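# Site-2-style scenario: long 66 h cultivation at pilot scale, feed start at
# 21 h, isoleucine co-feed, sparse offline assays, multiple tracked solutes.
site: 2
duration_h: 66.0
sampling_interval_h: 0.25
feed_start_h: 21.0
feed_start_range_h: [21.0, 21.0]
induction_time_h: 26.0
temperature_label: "28C"
initial:
  x0_g_l: 0.10
  s0_g_l: 10.0
  volume_l: 9.0
feed:
  glucose_rate_start_g_h: 4.0
  glucose_exp_rate_h: 0.03
  glucose_feed_conc_g_l: 400.0
  isoleucine_rate_g_h: 0.2
kinetics:
  mu_max: 0.18
  K_S: 0.05
  Y_XS: 0.50
  qs_crit: 0.30
  Y_AS: 0.55
  qac_max: 0.10
  K_A: 0.05
  Y_XA: 0.35
oxygen:
  alpha: 1.05
  beta: 0.02
  k_cX: 8.0
  X_cX: 0.0
  rq: 1.0
  rq_drift: 0.08
solutes:
  lactate:    {k_mu: 0.010, k_ind: 0.0005, k_cons: 0.020}
  glutamate:  {k_mu: 0.015, k_ind: 0.0010, k_cons: 0.015}
  glutamine:  {k_mu: 0.008, k_ind: 0.0015, k_cons: 0.010}
  isoleucine: {k_mu: 0.000, k_ind: 0.0000, k_cons: 0.008}
noise:
  our_rel_sd: 0.02
  cpr_rel_sd: 0.02
  broth_rel_sd: 0.005
  assay_rel_sd: 0.02
  assay_abs_sd_g_l: 0.005
assay:
  n_samples: 18
  first_sample_h: 2.0
broth_density_kg_l: 1.0
seed: 1
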