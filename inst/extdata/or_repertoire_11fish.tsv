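species	functional	functional_pct	partial	partial_pct	pseudogene	pseudogene_pct	total
Monopterus albus	289	90.88	10	3.14	19	5.97	318
Mastacembelus armatus	192	93.66	2	0.98	11	5.37	205
Betta splendens	114	96.61	4	3.39	0	0	118
Oreochromis niloticus	144	91.72	4	2.55	9	5.73	157
Oryzias latipes	82	95.35	1	1.16	3	3.49	86
Xiphophorus maculatus	99	94.29	1	0.95	5	4.76	105
Gadus morhua	87	95.60	1	1.10	3	3.30	91
Salmo salar	164	92.66	1	0.56	12	6.78	177
Ictalurus punctatus	89	94.68	2	2.13	3	3.19	94
Danio rerio	158	91.86	1	0.58	13	7.56	172
Scleropages formosus	119	95.20	6	4.80	0	0	125
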