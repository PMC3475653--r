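protein	impact_class	channels	weights
H-Ras	F	raf_activation;raf_deactivation	0.5;0.5
H-Ras	S	ras_activation;ras_inactivation	0.5;0.5
Raf-1	F	mek_activation	1
Raf-1	S	raf_activation	1
B-Raf	F	mek_activation	1
B-Raf	S	raf_activation	1
Mek	F	erk_activation	1
Mek	S	mek_activation	1
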