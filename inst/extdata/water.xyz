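3
water molecule, coordinates in Angstrom
O    0.0000    0.0000    0.0000
H    0.9572    0.0000    0.0000
H   -0.2400    0.9266    0.0000
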