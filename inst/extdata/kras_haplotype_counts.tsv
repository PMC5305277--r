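cell_line	replicate_id	wt_wt	wt_mut	mut_wt
HCT116	a	40	40	0
HCT116	b	36	34	0
HCT116	c	60	36	0
HKE3	a	82	46	35
HKE3	b	55	46	30
HKE3	c	32	62	44
HKE3	d	31	48	38
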