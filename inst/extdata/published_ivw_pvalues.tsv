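EXPOSURE	OUTCOME	P
glycine	AD	0.180
glycine	PD	0.531
glycine	ALS	0.916
glutamate	AD	0.004
glutamate	PD	0.209
glutamate	ALS	0.964
serotonin	AD	0.022
serotonin	PD	0.800
serotonin	ALS	0.312
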