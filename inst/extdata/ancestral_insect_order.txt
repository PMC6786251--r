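# Ancestral insect mitochondrial gene arrangement (the standard 37-gene
# ground plan, written from the conventional trnI origin; "-" = minority
# strand).  Control region excluded; it sits between rrnS and trnI.
trnI,-trnQ,trnM,ND2,trnW,-trnC,-trnY,COI,trnL2,COII,trnK,trnD,ATP8,ATP6,COIII,trnG,ND3,trnA,trnR,trnN,trnS1,trnE,-trnF,-ND5,-trnH,-ND4,-ND4L,trnT,-trnP,ND6,CYTB,trnS2,-ND1,-trnL1,-rrnL,-trnV,-rrnS
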