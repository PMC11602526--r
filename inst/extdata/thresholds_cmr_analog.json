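{
  "e_septal_low": {
    "value": 4,
    "op": "<="
  },
  "e_lateral_low": {
    "value": 9,
    "op": "<="
  },
  "E_low": {
    "value": 57,
    "op": "<="
  },
  "E_over_e_high": {
    "value": 12,
    "op": ">="
  },
  "E_over_A_high": {
    "value": 1.5,
    "op": ">="
  },
  "E_over_A_low": {
    "value": 0.9,
    "op": "<="
  },
  "lavi_high": {
    "value": 34,
    "op": ">="
  },
  "tr_velocity_high": {
    "value": 280,
    "op": ">"
  },
  "label": "CMR-paper"
}
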