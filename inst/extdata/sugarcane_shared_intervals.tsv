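hg	lg_ref	lg_cmp	n_intervals	ref_cm	cmp_cm
HG7	LG40	LG8	1	12.1	4.8
HG8	LG41	LG93	1	17.1	24.6
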