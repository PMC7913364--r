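locus	n_pcr	target_bp
PPT1	2	26746
ABCA4	8	137748
CRB1	14	212898
PCARE	1	18628
EFEMP1	5	60569
IMPG2	6	94768
PROM1	7	117712
MFSD8	3	49747
CTNNA1	13	182694
GUCA1A	2	27191
GUCA1B	1	13548
PRPH2	2	32242
IMPG1	11	144700
ELOVL4	2	34792
DHS6S1	1	13473
RP1L1	3	51877
RP1	1	16930
CNGB3	12	172052
KCNV2	1	15214
ATOH7	1	9275
PDE6C	3	53794
BEST1	1	17272
C1QTNF5	1	10536
PDE6H	1	11084
RDH5	1	6122
OTX2	1	12758
NR2E3	1	11097
RLBP1	1	13667
GUCY2D	1	18939
FSCN2	1	11574
RAX2	1	5845
TIMP3	5	67146
RS1	3	34731
RPGR	4	60808
RP2	3	46521
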