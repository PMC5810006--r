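gene	patient	chrom	pos	cytoband	substitution	exon	aa_change	consequence	sift	primary	axillary	metastasis_1	metastasis_2	note
AKAP3	pat19	chr12	4725047	12p13.32	G>A	5/5	Ser807Leu	nonsynonymous	damaging	0.02		0.13	0.41;0.22	metastasis_2 from multiple blocks of same sample
AKAP4	pat8	chrX	49958130	Xp11.22	A>G	5/6	Phe412Leu	nonsynonymous	damaging	0	0	0.22	0.26	metastasis_1 is locoregional
AKAP9	pat7	chr7	91630327	7q21.2	A>G	8/50	Ile366Val	nonsynonymous	tolerated	0.04		0.24;0.36		metastasis_1 from multiple blocks of same sample
AKAP11	pat12	chr13	42875448	13q14.11	G>A	8/13	Asp856Asn	nonsynonymous	tolerated	0		0.08
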