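inflammation	inflammation	IL6	IL8	IL10	IL12A	IL12B	IL18	CCL2	CRP	IFNG	MMP9	SPLA2	GGT5
coagulation	coagulation	F7	FGA	FGB	FGG	F2	PAI1	PLG	F3	VWF	PDGF
cell_adhesion	cell_adhesion	CLU	SELP
obesity	obesity	ADIPOQ	LEP
oxidative_stress	oxidative_stress	MPO
stress	stress	HSP27	HSP60	HSP70
renal_function	renal_function	CST3
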