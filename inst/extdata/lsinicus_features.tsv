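# organism=Labriocimbex_sinicus	accession=MH136623	length=15405	circular=true
# Published annotation ledger of the L. sinicus mitogenome (GenBank MH136623),
# transcribed to the canonical symbol vocabulary.  Declared Length, codons,
# Anticodon and IGN are carried as published, including internal
# inconsistencies (e.g. the trnT row and several anticodon entries), which the
# validator is expected to flag.  The published table assigns no strand to the
# AT-rich region; it is encoded here on J by convention.
Gene	Strand	Start	Stop	Length	StartCodon	StopCodon	Anticodon	IGN
trnI	J	1	67	67			GAU	1
ND2	J	70	1113	1044	ATG	TAA		2
trnW	J	1117	1181	65			UCA	3
COI	J	1182	2720	1539	ATT	TAA		0
trnL2	J	2760	2825	66			UAA	39
COII	J	2827	3510	684	ATG	TAA		1
trnK	J	3532	3602	71			CUU	21
trnD	J	3603	3672	70			GUC	0
ATP8	J	3673	3834	162	ATC	TAA		0
ATP6	J	3828	4517	690	ATG	TAA		-7
COIII	J	4504	5289	786	ATG	TAA		-14
trnG	J	5310	5373	64			UCC	20
ND3	J	5374	5724	351	ATT	TAA		0
trnA	J	5732	5797	66			UGC	7
trnR	J	5798	5864	67			UCG	0
trnN	J	5866	5934	69			GUU	1
trnS1	J	5935	6002	68			UGA	0
trnE	J	6010	6076	67			UUC	7
trnF	N	6092	6158	67			AAG	15
ND5	N	6159	7872	1714	ATT	T		0
trnH	N	7873	7940	68			GUG	0
ND4	N	7991	9343	1353	ATT	TAA		50
ND4L	N	9337	9618	282	ATT	TAA		-7
trnT	N	9621	9865	65			UGU	2
trnP	N	9686	9751	66			GGU	0
ND6	J	9753	10256	504	ATA	TAA		1
CYTB	J	10258	11391	1134	ATA	TAA		1
trnS2	J	11435	11502	68			UCU	43
ND1	N	11512	12462	951	ATT	TAA		9
trnL1	N	12463	12530	68			GAU	0
rrnL	N	12531	13871	1341				0
trnV	N	13872	13941	70			CAU	0
rrnS	N	13941	14731	791				-1
trnM	J	14777	14845	69			CAU	45
trnQ	N	14843	14911	69			GUU	-3
control_region	J	14912	15261	350				0
trnY	J	15262	15331	70			GUA	0
trnC	N	15333	15403	71			ACG	1
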