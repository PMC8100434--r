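pathway	category
CELL_CYCLE	oncogenic
HIPPO	oncogenic
MYC	oncogenic
NOTCH	oncogenic
NRF2	oncogenic
PI3K	oncogenic
RTK_RAS	oncogenic
TGFB	oncogenic
TP53	oncogenic
WNT	oncogenic
MMR	ddr
BER	ddr
CPF	ddr
FA	ddr
HRR	ddr
NER	ddr
NHEJ	ddr
TLS	ddr
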