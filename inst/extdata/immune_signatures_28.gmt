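Activated_CD8_T_cell	marker genes, curated stand-in	CD8A	CD8B	GZMA	GZMB	GZMH	PRF1	IFNG	KLRG1	CX3CR1	TBX21	EOMES	FASLG
Central_memory_CD8_T_cell	marker genes, curated stand-in	CD8A	CCR7	SELL	IL7R	TCF7	LEF1	CD27	CD28	BCL2
Effector_memory_CD8_T_cell	marker genes, curated stand-in	CD8A	GZMK	KLRB1	CXCR3	CCR5	CD44	PDCD1	LAG3	TIGIT
Activated_CD4_T_cell	marker genes, curated stand-in	CD4	CD69	IL2	IL2RA	CD40LG	ICOS	TNFRSF4	TNFRSF9	TNFRSF18	CD28	LTA
Central_memory_CD4_T_cell	marker genes, curated stand-in	CD4	CCR7	SELL	IL7R	TCF7	LEF1	CD27	FOXP1
Effector_memory_CD4_T_cell	marker genes, curated stand-in	CD4	CCR4	CCR6	CXCR5	KLRB1	IL4R	PRDM1	GATA3
T_follicular_helper_cell	marker genes, curated stand-in	CXCR5	BCL6	ICOS	PDCD1	IL21	CD200	SH2D1A	CXCL13
Gamma_delta_T_cell	marker genes, curated stand-in	TRGC1	TRGC2	TRDC	KLRC1	KLRD1	NKG7	CTSW
Type_1_T_helper_cell	marker genes, curated stand-in	TBX21	IFNG	IL12RB2	STAT4	CXCR3	CCR5	IL2	LTA
Type_17_T_helper_cell	marker genes, curated stand-in	RORC	IL17A	IL17F	IL21	IL22	IL23R	CCR6	STAT3
Type_2_T_helper_cell	marker genes, curated stand-in	GATA3	IL4	IL5	IL13	IL4R	CCR4	STAT6	PTGDR2
Regulatory_T_cell	marker genes, curated stand-in	FOXP3	IL2RA	CTLA4	IKZF2	TNFRSF18	ENTPD1	CCR8	IL10
Activated_B_cell	marker genes, curated stand-in	CD19	MS4A1	CD79A	CD79B	CD86	CD69	TNFRSF13B	AICDA
Immature_B_cell	marker genes, curated stand-in	CD19	CD38	IGLL1	VPREB1	RAG1	RAG2	CD24	MME
Memory_B_cell	marker genes, curated stand-in	CD19	CD27	CD40	MS4A1	TNFRSF13C	CR2	FCRL4
Natural_killer_cell	marker genes, curated stand-in	NCAM1	NKG7	KLRD1	KLRF1	NCR1	NCR3	GNLY	PRF1	KIR2DL1
CD56bright_natural_killer_cell	marker genes, curated stand-in	NCAM1	SELL	IL7R	XCL1	XCL2	GZMK	KLRC1
CD56dim_natural_killer_cell	marker genes, curated stand-in	FCGR3A	CX3CR1	GZMB	PRF1	KIR2DL3	KIR3DL1	S1PR5
Myeloid_derived_suppressor_cell	marker genes, curated stand-in	ITGAM	CD33	ARG1	NOS2	S100A8	S100A9	IL4R	STAT3	CD14
Natural_killer_T_cell	marker genes, curated stand-in	CD3E	NCAM1	ZBTB16	KLRB1	IL2RB	GZMA	SLAMF1
Activated_dendritic_cell	marker genes, curated stand-in	CD80	CD83	CD86	CCR7	LAMP3	IL12B	CD40	RELB
Plasmacytoid_dendritic_cell	marker genes, curated stand-in	CLEC4C	IL3RA	LILRA4	IRF7	TCF4	GZMB	PTCRA
Immature_dendritic_cell	marker genes, curated stand-in	CD1A	CD1C	ITGAX	CLEC10A	FCER1A	CD209	MRC1
Macrophage	marker genes, curated stand-in	CD68	CD163	MRC1	MSR1	MARCO	CSF1R	ITGAM	LYZ	APOE
Eosinophil	marker genes, curated stand-in	SIGLEC8	CCR3	IL5RA	EPX	PRG2	RNASE2	RNASE3	CLC
Mast_cell	marker genes, curated stand-in	KIT	TPSAB1	TPSB2	CPA3	MS4A2	CMA1	HDC	FCER1A
Monocyte	marker genes, curated stand-in	CD14	FCGR3A	CSF1R	LYZ	S100A12	VCAN	FCN1	CCR2
Neutrophil	marker genes, curated stand-in	FCGR3B	CSF3R	CXCR2	FPR1	S100A8	S100A9	ELANE	MPO	CEACAM8
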