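	normal	impaired
normal	74	1
impaired	4	39
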