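2
model charge-flux diatomic (synthetic fixture, bond = 2 Bohr)
H 0.0 0.0 0.0
H 0.0 0.0 1.0583544172
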