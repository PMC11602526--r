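{
  "e_septal_low": {
    "value": 7,
    "op": "<"
  },
  "e_lateral_low": {
    "value": 10,
    "op": "<"
  },
  "E_low": {
    "value": 50,
    "op": "<="
  },
  "E_over_e_high": {
    "value": 14,
    "op": ">"
  },
  "E_over_A_high": {
    "value": 2,
    "op": ">"
  },
  "E_over_A_low": {
    "value": 0.8,
    "op": "<"
  },
  "lavi_high": {
    "value": 34,
    "op": ">"
  },
  "tr_velocity_high": {
    "value": 280,
    "op": ">"
  },
  "label": "TTE-2016"
}
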