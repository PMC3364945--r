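Configuration keys for ip3rpuff JSON config files (see default-config.json).
JSON carries no comments, so units are documented here and in ?loadConfig.

Gating (DYK subunit cube; on-rates a_* in 1/(uM s), off-rates b_* in 1/s)
  a_act, b_act            activating Ca2+ site (K_act = b/a = 0.25 uM)
  a_inh_ip3, b_inh_ip3    inhibiting Ca2+ site when IP3 is bound
  a_inh_noip3, b_inh_noip3  inhibiting Ca2+ site when IP3 is not bound
  a_ip3_noninh, b_ip3_noninh  IP3 site when the inhibiting site is empty
  a_ip3_inh, b_ip3_inh    IP3 site when the inhibiting site is occupied
  Constraint: K_ip3_noninh * K_inh_ip3 = K_ip3_inh * K_inh_noip3
  (validated on load to 1e-6 relative).

Microdomain
  c0       uM   resting concentration
  c1       uM   coupling concentration per open channel
  c_high   uM   pore concentration felt by an open channel
  k        1/s  collapse rate of residual Ca2+ (100 = buffered/EGTA-like,
                10 = unbuffered)

Run
  n_channels     channels per cluster (20)
  ip3      uM    IP3 concentration
  dt       s     stochastic time step (max rate * dt <= 0.1 enforced)
  record_dt s    sampling interval (integer multiple of dt)
  duration s     recorded duration
  burn_in  s     discarded initial transient
  seed           integer RNG seed (reproduces the trace bit-for-bit)

Any key may be omitted; missing keys take the package defaults.
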