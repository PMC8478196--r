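# Adex cell-type presets (paper units: pF, nS, mV, ms, pA).
# FS2 shares the FS parameters; it differs only in connectivity.
RS:
  V_th: -40
  delta: 2
  T_ref: 5
  tau_w: 500
  a: 4
  b: 20
  C: 150
  g_L: 10
  E_L: -65
  E_E: 0
  E_I: -80
  V_rest: -65
FS:
  V_th: -47.5
  delta: 0.5
  T_ref: 5
  tau_w: 500
  a: 0
  b: 0
  C: 150
  g_L: 10
  E_L: -65
  E_E: 0
  E_I: -80
  V_rest: -65
Ch:
  V_th: -47.5
  delta: 0.5
  T_ref: 1
  tau_w: 50
  a: 80
  b: 150
  C: 150
  g_L: 10
  E_L: -58
  E_E: 0
  E_I: -80
  V_rest: -65
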