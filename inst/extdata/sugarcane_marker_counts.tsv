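system	n_scored	n_sd
DArT	1246	1018
AFLP	1062	770
SSR	598	473
SNP	184	153
RAPD	43	26
RFLP	33	27
Total	3182	2467
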