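scaf1	0	100000	scaf1_g0001
scaf1	100000	200000	scaf1_g0002
scaf1	200000	300000	scaf1_g0003
scaf1	300000	400000	scaf1_g0004
scaf1	400000	500000	scaf1_g0005
scaf1	500000	600000	scaf1_g0006
scaf2	0	100000	scaf2_g0001
scaf2	100000	200000	scaf2_g0002
scaf2	200000	300000	scaf2_g0003
scaf2	300000	400000	scaf2_g0004
scaf2	400000	500000	scaf2_g0005
scaf2	500000	600000	scaf2_g0006
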