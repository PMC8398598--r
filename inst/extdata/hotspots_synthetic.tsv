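gene	chrom	pos	ref	alt	protein_change	tier
ALK	chr2s	61174	C	A	F1174L	1
ALK	chr2s	61275	G	A	R1275Q	1
TP53	chr17s	5000	C	T	R175H	1
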