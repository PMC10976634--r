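3
water, experimental equilibrium geometry
O   0.000000   0.000000   0.000000
H   0.756970   0.000000   0.585883
H  -0.756970   0.000000   0.585883
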