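# contig	start	end	locus	amplicon	score	fwd_primer	rev_primer
toy1	0	12000	LOC_A	A_1	0	1-28	11973-12000
toy1	11800	23500	LOC_A	A_2	0	11801-11828	23473-23500
toy1	23300	30000	LOC_A	A_3	0	23301-23328	29973-30000
toy2	1000	9500	LOC_B	B_1	0	1001-1028	9473-9500
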