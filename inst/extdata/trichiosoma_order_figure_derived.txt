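# Trichiosoma anthracinum gene order, SYNTHETIC transcription from a published
# genome-organization figure (the order is not printed as text anywhere).
# Figure-derived; excluded from numeric acceptance checks.  Relative to the
# ancestral plan the trnW-trnC-trnY cluster is rearranged: trnY is remotely
# inverted to the segment upstream of trnI and trnC translocated with it.
trnI,-trnQ,trnM,ND2,trnW,COI,trnL2,COII,trnK,trnD,ATP8,ATP6,COIII,trnG,ND3,trnA,trnR,trnN,trnS1,trnE,-trnF,-ND5,-trnH,-ND4,-ND4L,trnT,-trnP,ND6,CYTB,trnS2,-ND1,-trnL1,-rrnL,-trnV,-rrnS,trnY,-trnC
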