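# Published nucleotide-composition table of the L. sinicus mitogenome
# (percentages as printed; skew columns as printed, recomputable from the
# percentage columns).  Used as a numeric input fixture only: the published
# PCG totals are known to disagree with sums over the feature ledger and are
# never asserted against recomputed per-sequence values.
Region	Length	A	C	G	T	AT	ATskew	GCskew
whole_genome	15405	43.5	11.1	7.7	37.7	81.2	0.0714	-0.1809
PCG_all	12456	34.4	9.7	10.4	45.5	79.9	-0.1389	0.0348
PCG_all_pos1	4152	36.9	9.5	15.1	38.5	75.4	-0.0212	0.2276
PCG_all_pos2	4152	20.9	16.2	13	49.9	70.8	-0.4096	-0.1096
PCG_all_pos3	4152	45.5	3.5	3	48	93.5	-0.0267	-0.0769
PCG_J	6840	37.8	12	9.3	40.9	78.7	-0.0394	-0.1268
PCG_J_pos1	2280	40.4	11.9	14.6	33.1	73.5	0.0993	0.1019
PCG_J_pos2	2280	23	18.7	12	46.3	69.3	-0.3362	-0.2182
PCG_J_pos3	2280	50	5.3	1.4	43.3	93.3	0.0718	-0.5821
PCG_N	5616	30.3	7	11.6	51.1	81.4	-0.2555	0.2473
PCG_N_pos1	1872	32.5	6.7	15.6	45.2	77.7	-0.1634	0.3991
PCG_N_pos2	1872	18.4	13.1	14.3	54.3	72.7	-0.4938	0.0438
PCG_N_pos3	1872	40.1	1.2	5	53.7	93.8	-0.1450	0.6129
ATP6	690	38.3	11.2	8	42.6	80.9	-0.0532	-0.1667
ATP8	162	45.1	9.3	2.5	43.2	88.3	0.0215	-0.5763
ND1	951	51.4	12.3	6.9	29.3	80.7	0.2739	-0.2813
ND2	1044	44.1	9.9	5.7	40.3	84.4	0.0450	-0.2692
ND3	351	35	10.5	9.7	44.7	79.7	-0.1217	-0.0396
ND4	1353	51.2	11.5	7.4	29.9	81.1	0.2626	-0.2169
ND4L	282	49.6	12.1	3.5	34.8	84.4	0.1754	-0.5513
ND5	1714	50.8	11.1	6.8	31.3	82.1	0.2375	-0.2402
ND6	504	42.1	8.7	5	44.2	86.3	-0.0243	-0.2701
COI	1539	35.1	13.5	12.8	38.7	73.8	-0.0488	-0.0266
COII	684	40.8	12.7	8	38.5	79.3	0.0290	-0.2271
COIII	786	33.5	13	12	41.6	75.1	-0.1079	-0.0400
CYTB	1134	35.4	13.1	10.4	41.2	76.6	-0.0757	-0.1149
rrnS	791	44	10.7	5.3	40.1	84.1	0.0464	0.3375
rrnL	1341	46.8	11	4.9	37.4	84.2	0.1116	-0.3836
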