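group,n,n_female,n_smoking
NW,30,19,7
OB_METS_NEG,24,18,9
OB_METS_POS,30,19,9
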