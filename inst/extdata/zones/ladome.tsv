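symbol
LMNA
LBR
EMD
CBX1
SMCHD1
RIF1
PRR14
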