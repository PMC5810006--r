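gene	n_amp_both_compartments	n_del_both_compartments	n_del_metastasis_only
AKAP1	10	0	0
AKAP12	0	2	1
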