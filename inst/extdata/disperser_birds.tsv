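name	body_mass_g
brown-eared bulbul	67
Japanese wood pigeon	550
jungle crow	1100
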