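# Template for a MAPK-structured model variant (synthetic placeholder).
# Fill in all twelve rate constants and nine initial concentrations, e.g.
# with an alternative experimentally measured initial-condition set, then
# load with load_model_variant("<this file>").
name: mapk_variant_user
horizon: 100
params:
  c_1: ~
  c_2: ~
  c_3: ~
  c_4: ~
  c_5: ~
  c_6: ~
  c_7: ~
  c_8: ~
  c_9: ~
  c_10: ~
  c_11: ~
  c_12: ~
initial_conditions:
  ShcGS: ~
  RasGDP: ~
  RasGTP: ~
  Raf: ~
  Raf_a: ~
  Mek: ~
  Mek_a: ~
  Erk: ~
  Erk_a: ~
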