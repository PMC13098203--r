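amino_acid	fraction
glu__L	0.647
leu__L	0.25
met__L	0.1
cys__L	0.003
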