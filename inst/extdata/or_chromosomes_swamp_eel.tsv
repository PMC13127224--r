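chrom	size_mb	functional	partial	pseudogene	total
Chr1	87.97	5	0	0	5
Chr2	90.20	17	0	2	19
Chr3	76.37	6	0	0	6
Chr4	73.15	33	4	1	38
Chr5	70.33	7	2	0	9
Chr6	68.68	8	0	1	9
Chr7	63.48	2	0	0	2
Chr8	65.39	65	0	6	71
Chr9	60.65	48	2	0	50
Chr10	51.71	9	0	0	9
Chr11	55.67	24	0	3	27
Chr12	49.80	65	2	6	73
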