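gene	chrom	start	end	strand
MYCN	chr2s	30000	33000	+
ALK	chr2s	60000	64000	+
TERT	chr5s	50000	53000	+
ATRX	chrXs	20000	24000	+
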