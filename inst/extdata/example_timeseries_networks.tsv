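parcel	network
p001	DMN
p002	VIS
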