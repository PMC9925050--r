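{
  "BurstIE": {
    "nu_h": 6.4, "nu_l": 2.8,
    "nu_bh": 2.4, "nu_bl": 2.3, "nu_bi": 3.1,
    "s": 1.13, "T_ac_ms": 90, "b_range_ms": 72,
    "beta_rate": 54.9, "n_shape": 6.9,
    "T_rh_ms": 86, "T_rl_ms": 85, "T_ri_ms": 95,
    "s_u": 0.42, "s_t_ms": 65
  },
  "SustIE": {
    "nu_h": 8.4, "nu_l": 3.3,
    "nu_bh": 0.63, "nu_bl": 0.49, "nu_bi": 0.74,
    "s": 1.16, "T_ac_ms": 90,
    "beta_rate": 41.4, "n_shape": 6.7,
    "T_rh_ms": 72, "T_rl_ms": 67, "T_ri_ms": 79,
    "s_u": 0.46, "s_t_ms": 65
  },
  "BurstSE": {
    "nu_h": 4.9, "nu_l": 2.1,
    "nu_bh": 2.3, "nu_bl": 2.4, "nu_bi": 3.1,
    "s": 0.93, "T_ac_ms": 91, "b_range_ms": 72,
    "T_ev_ms": 205,
    "T_rh_ms": 73, "T_rl_ms": 74, "T_ri_ms": 84,
    "s_u": 0.39, "s_t_ms": 81
  },
  "SustSE": {
    "nu_h": 4.6, "nu_l": 2.1,
    "nu_bh": 0.51, "nu_bl": 0.46, "nu_bi": 0.63,
    "s": 0.81, "T_ac_ms": 91,
    "T_ev_ms": 223,
    "T_rh_ms": 57, "T_rl_ms": 54, "T_ri_ms": 63,
    "s_u": 0.4, "s_t_ms": 80
  }
}
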