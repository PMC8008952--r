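symbol
LMNA
LMNB1
LBR
EMD
TMPO
NUP153
NUP93
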