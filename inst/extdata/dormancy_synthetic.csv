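genotype,photoperiod,replicate,n_dissected,n_arrested
wildtype,LD16_8,rep01,60,15
wildtype,LD16_8,rep02,60,12
wildtype,LD16_8,rep03,60,12
wildtype,LD16_8,rep04,60,13
wildtype,LD16_8,rep05,60,8
wildtype,SD8_16,rep01,60,33
wildtype,SD8_16,rep02,60,41
wildtype,SD8_16,rep03,60,31
wildtype,SD8_16,rep04,60,36
wildtype,SD8_16,rep05,60,34
pdf_overexpression,LD16_8,rep01,60,6
pdf_overexpression,LD16_8,rep02,60,4
pdf_overexpression,LD16_8,rep03,60,1
pdf_overexpression,LD16_8,rep04,60,7
pdf_overexpression,LD16_8,rep05,60,4
pdf_overexpression,SD8_16,rep01,60,13
pdf_overexpression,SD8_16,rep02,60,13
pdf_overexpression,SD8_16,rep03,60,19
pdf_overexpression,SD8_16,rep04,60,18
pdf_overexpression,SD8_16,rep05,60,9
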