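	normal	obstructive	spirometric_restriction
normal	74	1	0
obstructive	1	23	1
spirometric_restriction	3	1	14
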