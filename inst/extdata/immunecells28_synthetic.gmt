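Activated_CD8_T_cell	synthetic surrogate marker list	CD8A	CD8B	GZMA	GZMB	PRF1
Central_memory_CD8_T_cell	synthetic surrogate marker list	CD8A	CCR7	SELL	IL7R	TCF7
Effector_memory_CD8_T_cell	synthetic surrogate marker list	CD8A	GZMK	KLRG1	CXCR3	EOMES
Activated_CD4_T_cell	synthetic surrogate marker list	CD4	IL2RA	CD69	ICOS	CD40LG
Central_memory_CD4_T_cell	synthetic surrogate marker list	CD4	CCR7	SELL	TCF7	LEF1
Effector_memory_CD4_T_cell	synthetic surrogate marker list	CD4	CCR5	CXCR3	KLRB1	IL7R
T_follicular_helper_cell	synthetic surrogate marker list	CXCR5	BCL6	ICOS	PDCD1	IL21
Gamma_delta_T_cell	synthetic surrogate marker list	TRGC1	TRGC2	TRDC	KLRC1	NKG7
Type_1_T_helper_cell	synthetic surrogate marker list	TBX21	IFNG	IL12RB2	STAT4	CXCR3
Type_2_T_helper_cell	synthetic surrogate marker list	GATA3	IL4	IL5	IL13	CCR4
Type_17_T_helper_cell	synthetic surrogate marker list	RORC	IL17A	IL17F	IL23R	CCR6
Regulatory_T_cell	synthetic surrogate marker list	FOXP3	IL2RA	CTLA4	IKZF2	TNFRSF18
Activated_B_cell	synthetic surrogate marker list	CD19	MS4A1	CD79A	CD79B	CD86
Immature_B_cell	synthetic surrogate marker list	CD19	CD38	IGHM	IGHD	VPREB3
Memory_B_cell	synthetic surrogate marker list	CD27	CD19	MS4A1	TNFRSF13B	AIM2
Natural_killer_cell	synthetic surrogate marker list	NCAM1	KLRD1	NKG7	GNLY	KIR2DL1
CD56bright_natural_killer_cell	synthetic surrogate marker list	NCAM1	XCL1	XCL2	KLRC1	SELL
CD56dim_natural_killer_cell	synthetic surrogate marker list	FCGR3A	KIR2DL3	KIR3DL1	GZMB	SPON2
Natural_killer_T_cell	synthetic surrogate marker list	ZBTB16	KLRB1	CD3D	NCAM1	IL18RAP
Activated_dendritic_cell	synthetic surrogate marker list	CD83	CCR7	LAMP3	CD80	CD40
Plasmacytoid_dendritic_cell	synthetic surrogate marker list	CLEC4C	LILRA4	IL3RA	IRF7	GZMB
Immature_dendritic_cell	synthetic surrogate marker list	CD1A	CD1C	FCER1A	ITGAX	CLEC10A
Macrophage	synthetic surrogate marker list	CD68	CD163	MRC1	MSR1	CSF1R
Eosinophil	synthetic surrogate marker list	SIGLEC8	PRG2	EPX	IL5RA	CCR3
Mast_cell	synthetic surrogate marker list	TPSAB1	TPSB2	CPA3	MS4A2	KIT
Monocyte	synthetic surrogate marker list	CD14	FCN1	S100A8	S100A9	LYZ
Neutrophil	synthetic surrogate marker list	FCGR3B	CSF3R	CXCR2	FPR1	S100A12
Myeloid_derived_suppressor_cell	synthetic surrogate marker list	ARG1	NOS2	IL10	S100A8	CD33
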