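angiogenesis	synthetic surrogate marker list	VEGFA	KDR	FLT1	PECAM1	CDH5	ANGPT2	TEK	ENG	VWF	TIE1
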