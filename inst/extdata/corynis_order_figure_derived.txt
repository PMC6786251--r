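# Corynis lateralis gene order, SYNTHETIC transcription from a published
# genome-organization figure (the order is not printed as text anywhere).
# Figure-derived; excluded from numeric acceptance checks.  Encoded as
# retaining the ancestral arrangement.
trnI,-trnQ,trnM,ND2,trnW,-trnC,-trnY,COI,trnL2,COII,trnK,trnD,ATP8,ATP6,COIII,trnG,ND3,trnA,trnR,trnN,trnS1,trnE,-trnF,-ND5,-trnH,-ND4,-ND4L,trnT,-trnP,ND6,CYTB,trnS2,-ND1,-trnL1,-rrnL,-trnV,-rrnS
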