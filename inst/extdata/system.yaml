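drug:
  name: acetaminophen
  fu_adult:
    value: 0.82
    unit: fraction
  membrane_permeability:
    value: 0.00429
    unit: dm/min
  endothelial_permeability:
    value: 10.0
    unit: dm/min
  pKa: 9.380000000000001
  pka_type: acid
  logP: 0.46
  molecular_weight: 151.159999999999997
system:
  Q_M:
    value: 0.014
    unit: L/min
  Q_F:
    value: 0.006
    unit: L/min
  V_M_res:
    value: 0.28
    unit: L
  V_F_res:
    value: 0.284
    unit: L
  V_intervillous:
    value: 0.023
    unit: L
  V_intravillous:
    value: 0.035
    unit: L
  SA_villi:
    value: 33.657142857142858
    unit: dm^2
  fu:
    value: 0.842588543944031
    unit: fraction
  fu_fetus:
    value: 0.877105143377333
    unit: fraction
  K_M_int_perf:
    value: 0.869132601661565
    unit: unitless
  K_F_int_perf:
    value: 0.889579544833864
    unit: unitless
  K_F_cell_perf:
    value: 4.31
    unit: unitless
  K_FM_cell_perf:
    value: 4.31
    unit: unitless
  f_in:
    value: 0.06
    unit: unitless
  f_out:
    value: 0.051
    unit: unitless
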