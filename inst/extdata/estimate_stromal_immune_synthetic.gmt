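stromal	synthetic surrogate stromal signature	COL1A1	COL1A2	COL3A1	FAP	FN1	THY1	DCN	LUM	POSTN	ACTA2	PDGFRB	VIM
immune	synthetic surrogate immune signature	PTPRC	CD3D	CD3E	CD8A	CD19	MS4A1	CD14	FCGR3A	NKG7	GZMB	IL7R	CCL5
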