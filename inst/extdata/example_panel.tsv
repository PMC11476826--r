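# Miniature curated MSC gene panel in the panelqc TSV dialect.
# categories are ';'-separated functional labels; exclusion flags are 0/1.
symbol	gene_id	categories	excluded_high_expression	excluded_no_primer
IDO1	3620	immunoregulation;anti-inflammatory	0	0
PTGES	9536	immunoregulation	0	0
TGFB1	7040	immunoregulation;angiogenesis	0	0
HGF	3082	immunoregulation;fibrosis	0	0
PTGS2	5743	anti-inflammatory	0	0
TNFAIP6	7130	anti-inflammatory	0	0
VEGFA	7422	angiogenesis;neurogenesis;fibrosis	0	0
ANGPT1	284	angiogenesis	0	0
FGF2	2247	angiogenesis	0	0
BDNF	627	neurogenesis	0	0
NGF	4803	neurogenesis	0	0
ALPL	249	osteogenesis	0	0
COL1A1	1277	osteogenesis;chondrogenesis	0	0
PPARG	5468	adipogenesis	0	0
LPL	4023	adipogenesis	0	0
COL2A1	1280	chondrogenesis	0	0
ACAN	176	chondrogenesis	0	0
SOX9	6662	chondrogenesis	0	0
CXCR4	7852	migration	0	0
MMP2	4313	migration	0	0
ITGB1	3688	adhesion	0	0
VCAM1	7412	adhesion	0	0
CDKN2A	1029	senescence	0	0
CDKN1A	1026	senescence	0	0
CD274	29126	immunogenicity	0	0
ACTB	60	housekeeping	1	0
GAPDH	2597	housekeeping	1	0
OR2T1	26696	olfactory	0	1
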