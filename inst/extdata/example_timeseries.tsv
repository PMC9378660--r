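p001	p002
0.5	-1.25
1.5	2
-0.75	0.25
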