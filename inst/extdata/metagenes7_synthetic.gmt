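HCK	synthetic surrogate marker list	HCK	FGR	LYN	CSF1R	ITGAM	TYROBP
IgG	synthetic surrogate marker list	IGHM	IGKC	IGLC1	CD79A	CD79B	MZB1
LCK	synthetic surrogate marker list	LCK	CD3D	CD3E	CD2	ZAP70	ITK
MHC-I	synthetic surrogate marker list	HLA-A	HLA-B	HLA-C	B2M	TAP1	TAP2
MHC-II	synthetic surrogate marker list	HLA-DRA	HLA-DRB1	HLA-DPA1	HLA-DPB1	HLA-DQA1	CD74
Interferon	synthetic surrogate marker list	IFI27	IFI44	IFI44L	IFIT1	IFIT3	MX1	OAS1
STAT1	synthetic surrogate marker list	STAT1	IRF1	GBP1	GBP2	CXCL9	CXCL10
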