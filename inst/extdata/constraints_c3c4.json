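{
  "hi_blocked":  {"Z_c": 0.33, "Z_i": 0.12, "U_c": 1.24, "U_i": 1.66},
  "lo_blocked":  {"Z_c": 0.35, "Z_i": 0.06, "U_c": 0.95, "U_i": 1.61},
  "interleaved": {"Z_c": 0.2,  "Z_i": 0.0,  "U_c": 1.17, "U_i": 1.63}
}
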