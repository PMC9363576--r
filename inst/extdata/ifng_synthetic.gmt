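ifng	synthetic surrogate Th1/IFN-gamma response list	IFNG	STAT1	CXCL9	CXCL10	CXCL11	IDO1	HLA-DRA	GZMA	PRF1	TBX21
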