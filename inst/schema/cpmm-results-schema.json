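{
  "title": "cpmixed fit results",
  "required": ["model", "p_index", "n", "coefficients", "dispersion",
               "convergence"],
  "types": {
    "model": "string",
    "p_index": "number",
    "n": "object",
    "coefficients": "object",
    "dispersion": "object",
    "convergence": "object"
  }
}
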