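# Example coach configuration: any subset of fields may be given;
# omitted fields keep the package defaults (see ?nvc_config).
weights:
  w_n: 0.4
  w_a: 0.3
  w_u: 0.3
deadline: 15
concession_exponent: 1.5
tolerance: 0.12
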