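{
  "lambda_I": 0.09,
  "lambda_II": 0.19,
  "lambda_III": 0.04,
  "phi_I": 0.09,
  "phi_II": 0.21,
  "phi_III": 0.07
}
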