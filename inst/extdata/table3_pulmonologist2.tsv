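	normal	obstructive	spirometric_restriction	mixed
normal	75	0	0	0
obstructive	0	11	0	0
spirometric_restriction	1	0	14	3
mixed	0	1	0	13
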