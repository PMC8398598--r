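chr2s	30000	33000	MYCN
chr2s	60000	64000	ALK
chr5s	50000	53000	TERT
chrXs	20000	24000	ATRX
chr1s	10000	11000	1p36
chr1s	11200	12200	1p36
chr1s	12400	13400	1p36
chr1s	13600	14600	1p36
chr1s	14800	15800	1p36
chr1s	16000	17000	1p36
chr1s	17200	18200	1p36
chr1s	18400	19400	1p36
chr1s	19600	20600	1p36
chr1s	20800	21800	1p36
chr11s	10000	11000	11q
chr11s	11200	12200	11q
chr11s	12400	13400	11q
chr11s	13600	14600	11q
chr11s	14800	15800	11q
chr11s	16000	17000	11q
chr11s	17200	18200	11q
chr11s	18400	19400	11q
chr11s	19600	20600	11q
chr11s	20800	21800	11q
chr17s	10000	11000	17q
chr17s	11200	12200	17q
chr17s	12400	13400	17q
chr17s	13600	14600	17q
chr17s	14800	15800	17q
chr17s	16000	17000	17q
chr17s	17200	18200	17q
chr17s	18400	19400	17q
chr17s	19600	20600	17q
chr17s	20800	21800	17q
chr1s	40000	40120	REF_01
chr1s	41500	41620	REF_02
chr1s	43000	43120	REF_03
chr1s	44500	44620	REF_04
chr1s	46000	46120	REF_05
chr1s	47500	47620	REF_06
chr1s	49000	49120	REF_07
chr1s	50500	50620	REF_08
chr1s	52000	52120	REF_09
chr1s	53500	53620	REF_10
chr1s	55000	55120	REF_11
chr2s	80000	80120	REF_12
chr2s	81500	81620	REF_13
chr2s	83000	83120	REF_14
chr2s	84500	84620	REF_15
chr2s	86000	86120	REF_16
chr2s	87500	87620	REF_17
chr2s	89000	89120	REF_18
chr2s	90500	90620	REF_19
chr2s	92000	92120	REF_20
chr2s	93500	93620	REF_21
chr2s	95000	95120	REF_22
chr5s	80000	80120	REF_23
chr5s	81500	81620	REF_24
chr5s	83000	83120	REF_25
chr5s	84500	84620	REF_26
chr5s	86000	86120	REF_27
chr5s	87500	87620	REF_28
chr5s	89000	89120	REF_29
chr5s	90500	90620	REF_30
chr5s	92000	92120	REF_31
chr5s	93500	93620	REF_32
chr5s	95000	95120	REF_33
chr11s	30000	30120	REF_34
chr11s	31500	31620	REF_35
chr11s	33000	33120	REF_36
chr11s	34500	34620	REF_37
chr11s	36000	36120	REF_38
chr11s	37500	37620	REF_39
chr11s	39000	39120	REF_40
chr11s	40500	40620	REF_41
chr11s	42000	42120	REF_42
chr11s	43500	43620	REF_43
chr11s	45000	45120	REF_44
chr17s	30000	30120	REF_45
chr17s	31500	31620	REF_46
chr17s	33000	33120	REF_47
chr17s	34500	34620	REF_48
chr17s	36000	36120	REF_49
chr17s	37500	37620	REF_50
chr17s	39000	39120	REF_51
chr17s	40500	40620	REF_52
chr17s	42000	42120	REF_53
chr17s	43500	43620	REF_54
chr17s	45000	45120	REF_55
chrXs	40000	40120	REF_56
chrXs	41500	41620	REF_57
chrXs	43000	43120	REF_58
chrXs	44500	44620	REF_59
chrXs	46000	46120	REF_60
chrXs	47500	47620	REF_61
chrXs	49000	49120	REF_62
chrXs	50500	50620	REF_63
chrXs	52000	52120	REF_64
chrXs	53500	53620	REF_65
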