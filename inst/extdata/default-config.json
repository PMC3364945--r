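{
  "a_act": 80,
  "b_act": 20,
  "a_inh_ip3": 0.125,
  "b_inh_ip3": 2,
  "a_inh_noip3": 0.125,
  "b_inh_noip3": 0.013875,
  "a_ip3_noninh": 3,
  "b_ip3_noninh": 0.01456875,
  "a_ip3_inh": 0.45,
  "b_ip3_inh": 0.315,
  "c0": 0.02,
  "c1": 2.2,
  "c_high": 120,
  "k": 100,
  "n_channels": 20,
  "ip3": 0.07,
  "dt": 1e-05,
  "record_dt": 0.001,
  "duration": 400,
  "burn_in": 10,
  "seed": 1
}
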