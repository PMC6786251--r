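# Annotation-dialect synonyms for the canonical 37-gene insect mitogenome
# vocabulary.  Keys are canonical symbols; values are accepted aliases
# (matched case-insensitively).  Edit or extend freely.
ND1: [NAD1, NADH1, "NADH DEHYDROGENASE SUBUNIT 1"]
ND2: [NAD2, NADH2, "NADH DEHYDROGENASE SUBUNIT 2"]
ND3: [NAD3, NADH3, "NADH DEHYDROGENASE SUBUNIT 3"]
ND4: [NAD4, NADH4, "NADH DEHYDROGENASE SUBUNIT 4"]
ND4L: [NAD4L, NADH4L, "NADH DEHYDROGENASE SUBUNIT 4L"]
ND5: [NAD5, NADH5, "NADH DEHYDROGENASE SUBUNIT 5"]
ND6: [NAD6, NADH6, "NADH DEHYDROGENASE SUBUNIT 6"]
COI: [COX1, CO1, COXI, "CYTOCHROME C OXIDASE SUBUNIT 1", "CYTOCHROME C OXIDASE SUBUNIT I"]
COII: [COX2, CO2, COXII, "CYTOCHROME C OXIDASE SUBUNIT 2", "CYTOCHROME C OXIDASE SUBUNIT II"]
COIII: [COX3, CO3, COXIII, "CYTOCHROME C OXIDASE SUBUNIT 3", "CYTOCHROME C OXIDASE SUBUNIT III"]
ATP6: [ATPASE6, "ATP SYNTHASE F0 SUBUNIT 6"]
ATP8: [ATPASE8, "ATP SYNTHASE F0 SUBUNIT 8"]
CYTB: [COB, CYB, "CYTOCHROME B"]
rrnS: [12S, SRRNA, S-RRNA, RRN12, "12S RIBOSOMAL RNA", "SMALL SUBUNIT RIBOSOMAL RNA"]
rrnL: [16S, LRRNA, L-RRNA, RRN16, "16S RIBOSOMAL RNA", "LARGE SUBUNIT RIBOSOMAL RNA"]
control_region: [AT-RICH REGION, "AT RICH REGION", D-LOOP, "CONTROL REGION", CR]
trnA: [TRN-A, TRNA-ALA, "TRNA ALA"]
trnR: [TRNA-ARG, "TRNA ARG"]
trnN: [TRNA-ASN, "TRNA ASN"]
trnD: [TRNA-ASP, "TRNA ASP"]
trnC: [TRNA-CYS, "TRNA CYS"]
trnQ: [TRNA-GLN, "TRNA GLN"]
trnE: [TRNA-GLU, "TRNA GLU"]
trnG: [TRNA-GLY, "TRNA GLY"]
trnH: [TRNA-HIS, "TRNA HIS"]
trnI: [TRNA-ILE, "TRNA ILE"]
trnK: [TRNA-LYS, "TRNA LYS"]
trnM: [TRNA-MET, "TRNA MET"]
trnF: [TRNA-PHE, "TRNA PHE"]
trnP: [TRNA-PRO, "TRNA PRO"]
trnT: [TRNA-THR, "TRNA THR"]
trnW: [TRNA-TRP, "TRNA TRP"]
trnV: [TRNA-VAL, "TRNA VAL"]
trnL1: [TRNA-LEU1, TRNL-CUN, "TRNA-LEU (CUN)"]
trnL2: [TRNA-LEU2, TRNL-UUR, "TRNA-LEU (UUR)"]
trnS1: [TRNA-SER1, TRNS-AGN, "TRNA-SER (AGN)"]
trnS2: [TRNA-SER2, TRNS-UCN, "TRNA-SER (UCN)"]
trnY: [TRNA-TYR, "TRNA TYR"]
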