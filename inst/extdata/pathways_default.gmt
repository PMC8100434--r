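CELL_CYCLE	oncogenic signaling: cell cycle (curated stand-in)	CDKN2A	CDKN2B	CDKN2C	CDKN1A	CDKN1B	CCND1	CCND2	CCND3	CCNE1	CDK2	CDK4	CDK6	RB1	E2F1	E2F3
HIPPO	oncogenic signaling: Hippo (curated stand-in)	STK3	STK4	SAV1	LATS1	LATS2	MOB1A	MOB1B	YAP1	WWTR1	TEAD1	TEAD2	TEAD3	TEAD4	NF2	WWC1	TAOK1	TAOK2	TAOK3	CRB1	CRB2	DCHS1	DCHS2	FAT1	FAT2	FAT3	FAT4	CSNK1D	CSNK1E	AJUBA	LIMD1	WTIP
MYC	oncogenic signaling: Myc (curated stand-in)	MYC	MYCN	MYCL	MAX	MXD1	MXD3	MXD4	MXI1	MNT	MGA	MLX	MLXIP	MLXIPL
NOTCH	oncogenic signaling: Notch (curated stand-in)	NOTCH1	NOTCH2	NOTCH3	NOTCH4	JAG1	JAG2	DLL1	DLL3	DLL4	MAML1	MAML2	MAML3	RBPJ	HES1	HEY1	HEY2	HEYL	ADAM10	ADAM17	PSEN1	PSEN2	NCSTN	APH1A	LFNG	MFNG	RFNG	DTX1	DTX2	DTX3	DTX4	NUMB	NUMBL	FBXW7	EP300	CREBBP	KAT2B	SPEN	CTBP1	CTBP2
NRF2	oncogenic signaling: oxidative stress response/Nrf2 (curated stand-in)	NFE2L2	KEAP1	CUL3
PI3K	oncogenic signaling: PI-3-kinase (curated stand-in)	PIK3CA	PIK3CB	PIK3R1	PIK3R2	PIK3R3	PTEN	AKT1	AKT2	AKT3	MTOR	RICTOR	RPTOR	TSC1	TSC2	STK11	INPP4B	PPP2R1A	DEPDC5	DEPTOR
RTK_RAS	oncogenic signaling: RTK/RAS/MAP-kinase (curated stand-in)	EGFR	ERBB2	ERBB3	ERBB4	MET	ALK	ROS1	RET	FGFR1	FGFR2	FGFR3	FGFR4	PDGFRA	PDGFRB	KIT	IGF1R	KRAS	HRAS	NRAS	RIT1	ARAF	BRAF	RAF1	MAP2K1	MAP2K2	MAPK1	NF1	RASA1	SOS1	PTPN11	JAK2	CBL
TGFB	oncogenic signaling: TGF-beta (curated stand-in)	TGFBR1	TGFBR2	ACVR2A	ACVR1B	SMAD2	SMAD3	SMAD4
TP53	oncogenic signaling: p53 (curated stand-in)	TP53	MDM2	MDM4	ATM	CHEK2	RPS6KA3
WNT	oncogenic signaling: beta-catenin/Wnt (curated stand-in)	CTNNB1	APC	AXIN1	AXIN2	TCF7L2	GSK3B	AMER1	RNF43	ZNRF3	LRP5	LRP6	DKK1	DKK2	DKK3	DKK4	WIF1	SFRP1	SFRP2	SFRP4	SFRP5	TLE1	TLE2	TLE3	WNT1	WNT2	WNT3	WNT4	WNT5A
MMR	DDR: mismatch repair (curated stand-in)	MLH1	MLH3	MSH2	MSH3	MSH6	PMS1	PMS2	EXO1	PCNA	RFC1
BER	DDR: base excision repair (curated stand-in)	APEX1	APEX2	LIG3	MUTYH	NEIL1	NEIL2	NEIL3	NTHL1	OGG1	PARP1	PARP2	POLB	SMUG1	UNG	XRCC1	MBD4	TDG
CPF	DDR: check point factors (curated stand-in)	ATM	ATR	CHEK1	CHEK2	ATRIP	RAD17	RAD9A	RAD1	HUS1	TOPBP1	CLSPN	TIMELESS	TIPIN
FA	DDR: Fanconi anemia (curated stand-in)	FANCA	FANCB	FANCC	FANCD2	FANCE	FANCF	FANCG	FANCI	FANCL	FANCM	PALB2	BRIP1	UBE2T	SLX4	XRCC2
HRR	DDR: homologous recombination repair (curated stand-in)	BRCA1	BRCA2	RAD50	RAD51	RAD51B	RAD51C	RAD51D	RAD52	RAD54B	RAD54L	MRE11	NBN	BLM	WRN	BARD1	XRCC3
NER	DDR: nucleotide excision repair (curated stand-in)	ERCC1	ERCC2	ERCC3	ERCC4	ERCC5	ERCC6	ERCC8	XPA	XPC	DDB1	DDB2	CUL4A	CETN2	RAD23A	RAD23B
NHEJ	DDR: non-homologous end-joining (curated stand-in)	XRCC4	XRCC5	XRCC6	PRKDC	LIG4	NHEJ1	DCLRE1C	POLL	POLM
TLS	DDR: DNA translesion synthesis (curated stand-in)	POLH	POLI	POLK	POLQ	POLN	REV1	REV3L	MAD2L2	SHPRH	HLTF
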