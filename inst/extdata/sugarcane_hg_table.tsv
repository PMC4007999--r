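hg	n_lg	n_markers	length_cm
HG1	17	282	1253.4
HG2	23	475	1818.0
HG3	20	218	1243.6
HG4	18	305	1210.7
HG5	13	222	846.6
HG6	18	232	678.3
HG7	16	204	1020.5
HG8	22	295	1319.2
Unassigned	13	34	384.1
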