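# Published codon-usage table of the 13 L. sinicus mitochondrial PCGs under
# the invertebrate mitochondrial code (counts and printed RSCU).  Stop codons
# are printed with count 0 (terminal stops were not tallied).
AminoAcid	Codon	Count	RSCU
Phe	TTT	409	1.9
Phe	TTC	21	0.1
Leu	TTA	560	5.04
Leu	TTG	35	0.31
Leu	CTT	37	0.33
Leu	CTC	0	0
Leu	CTA	34	0.31
Leu	CTG	1	0.01
Ile	ATT	464	1.87
Ile	ATC	31	0.13
Met	ATA	314	1.91
Met	ATG	15	0.09
Val	GTT	83	2.21
Val	GTC	1	0.03
Val	GTA	65	1.73
Val	GTG	1	0.03
Ser	TCT	134	2.67
Ser	TCC	4	0.08
Ser	TCA	116	2.31
Ser	TCG	2	0.04
Pro	CCT	64	1.97
Pro	CCC	15	0.46
Pro	CCA	48	1.48
Pro	CCG	3	0.09
Thr	ACT	70	1.74
Thr	ACC	8	0.2
Thr	ACA	82	2.04
Thr	ACG	1	0.02
Ala	GCT	65	2.08
Ala	GCC	7	0.22
Ala	GCA	49	1.57
Ala	GCG	4	0.13
Tyr	TAT	159	1.78
Tyr	TAC	20	0.22
End	TAA	0	0
End	TAG	0	0
His	CAT	68	1.79
His	CAC	8	0.21
Gln	CAA	61	1.85
Gln	CAG	5	0.15
Asn	AAT	237	1.84
Asn	AAC	20	0.16
Lys	AAA	135	1.88
Lys	AAG	9	0.13
Asp	GAT	62	1.82
Asp	GAC	6	0.18
Glu	GAA	72	1.85
Glu	GAG	6	0.15
Cys	TGT	37	1.95
Cys	TGC	1	0.05
Trp	TGA	92	1.8
Trp	TGG	10	0.2
Arg	CGT	20	1.54
Arg	CGC	0	0
Arg	CGA	31	2.38
Arg	CGG	1	0.08
Ser	AGT	23	0.46
Ser	AGC	1	0.02
Ser	AGA	119	2.37
Ser	AGG	2	0.04
Gly	GGT	62	1.22
Gly	GGC	1	0.02
Gly	GGA	112	2.2
Gly	GGG	29	0.57
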