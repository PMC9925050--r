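{
  "hi_blocked":  {"Z_c": 0.33, "Z_i": 0.14,  "U_c": 1.33, "U_i": 1.78},
  "lo_blocked":  {"Z_c": 0.3,  "Z_i": 0.003, "U_c": 1.06, "U_i": 1.66},
  "interleaved": {"Z_c": 0.2,  "Z_i": 0.0,   "U_c": 1.26, "U_i": 1.76}
}
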