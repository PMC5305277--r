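cell_line	cosmic_snvs	rnaseq_snvs
COLO205	241	68
DLD1	7649	2239
HCT15	7649	3356
HCT116a	2428	1122
HCT116b	2428	1003
HKE3	2428	1379
HT29	462	145
RKO	2676	1112
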