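{
  "sites": ["I", "II", "III", "IV"],
  "primary_edges": {"I": "lambda_I", "II": "lambda_II", "III": "lambda_III"},
  "secondary_edges": [
    {"from": "I", "to": "II", "symbol": "phi_I"},
    {"from": "II", "to": "III", "symbol": "phi_II"},
    {"from": "III", "to": "IV", "symbol": "phi_III"}
  ]
}
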