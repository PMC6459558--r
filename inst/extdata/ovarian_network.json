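{
  "sites": ["LN", "lung", "liver", "bone", "brain"],
  "primary_edges": {"LN": "lambda_1", "lung": "lambda_2"},
  "secondary_edges": [
    {"from": "LN", "to": "lung", "symbol": "phi_1"},
    {"from": "lung", "to": "liver", "symbol": "phi_2"},
    {"from": "lung", "to": "bone", "symbol": "phi_3"},
    {"from": "lung", "to": "brain", "symbol": "phi_4"}
  ]
}
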