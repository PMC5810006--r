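gene	patient	compartment	call
AKAP7	P1	primary	deletion
AKAP7	P1	metastasis	deletion
AKAP7	P2	metastasis	deletion
AKAP7	P5	primary	deletion
AKAP7	P5	metastasis	deletion
AKAP12	P1	primary	deletion
AKAP12	P1	metastasis	deletion
AKAP12	P2	metastasis	deletion
AKAP12	P5	primary	deletion
AKAP12	P5	metastasis	deletion
AKAP11	P1	primary	deletion
AKAP11	P1	metastasis	deletion
AKAP11	P3	metastasis	deletion
AKAP11	P8	metastasis	deletion
AKAP8	P4	metastasis	amplification
AKAP1	P4	metastasis	amplification
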