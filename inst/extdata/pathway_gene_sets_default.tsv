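pathway	gene
RAS_MAPK	ALK
RAS_MAPK	NRAS
RAS_MAPK	KRAS
RAS_MAPK	HRAS
RAS_MAPK	BRAF
RAS_MAPK	RAF1
RAS_MAPK	NF1
RAS_MAPK	PTPN11
RAS_MAPK	FGFR1
p53_MDM2	TP53
p53_MDM2	MDM2
p53_MDM2	PPM1D
p53_MDM2	CDKN2A
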