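nk_signature_core10	Ten-gene core of a colorectal-cancer NK cell signature (published main-text subset)	ADGRB2	B4GALT6	LDB2	LIM2	LINC01451	LRRC43	PCDH1	PRSS57	RAMP1	RNF165
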