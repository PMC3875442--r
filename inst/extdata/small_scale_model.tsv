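w_1	w_2	w_3	w_4	b	k1	k2
20	-20	0	0	0	0.1	0.1
15	-10	0	0	-5	0.2	0.2
0	-8	12	0	0	0.2	0.2
0	0	8	-12	0	0.2	0.2
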