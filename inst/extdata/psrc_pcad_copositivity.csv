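quantity,count
pSRC_positive_tumors,41
pSRC_and_Pcad_positive,18
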