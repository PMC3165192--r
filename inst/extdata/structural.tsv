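name_a	name_b	t
Wogonin	Fisetin	0.75
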