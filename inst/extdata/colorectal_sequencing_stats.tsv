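cell_line	replicates	read_design	total_reads	total_snvs
COLO205	3	50x1	89964067	38777
DLD1	2	69x1	37087864	72203
HCT116a	3	100x2	98756403	177948
HCT116b	3	50x1	96249743	44231
HCT15	3	50x1	97492596	55195
HKE3	4	125x2	255394483	670153
HT29	3	50x1	87846283	38456
RKO	3	100x2	103479468	250042
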