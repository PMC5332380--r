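group	TC	TG	HDL	LDL
sham	0.75	0.064	0.54	0.03
model	1.30	0.26	0.34	0.064
treated	0.84	0.14	0.44	0.01
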