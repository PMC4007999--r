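hg	n_lg_in_repulsion	n_lg_no_repulsion
HG1	3	14
HG2	5	18
HG3	0	20
HG4	2	16
HG5	5	8
HG6	7	11
HG7	4	12
HG8	4	18
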