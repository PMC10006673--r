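gene	fpkm
g1	1
g2	1
g3	10
g4	1
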