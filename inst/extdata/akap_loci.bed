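chr17	55150000	55300000	AKAP1
chr14	64900000	64970000	AKAP5
chr14	33200000	33400000	AKAP6
chr6	130400000	130600000	AKAP7
chr19	15400000	15530000	AKAP8
chr13	42800000	42960000	AKAP11
chr6	151560000	151750000	AKAP12
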