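{
  "DDM": {
    "nu_h": 6.34, "nu_l": 3.5,
    "a_h": 0.17, "a_l": 0.18, "a_i": 0.16,
    "zb_h": 0.12, "zb_l": 0.1, "zb_i": 0.11,
    "Ter_h_s": 0.27, "Ter_l_s": 0.3, "Ter_i_s": 0.31,
    "s_z": 0.09, "s_t_s": 0.13, "eta": 6.39, "sigma": 0.1
  }
}
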