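gene_id	site_class	b73_ins	mo17_ins	b73_noins	mo17_noins
Zm00001d020901	five_prime_UTR	0	247	461	519
Zm00001d027950	intron	2	517	221	285
Zm00001d039733	five_prime_UTR	39	960	553	480
Zm00001d044446	five_prime_UTR	31	703	148	144
Zm00001d028712	five_prime_UTR	270	510	192	30
Zm00001d006460	five_prime_UTR	86	102	50	5
Zm00001d017424	five_prime_UTR	6	34	819	1065
Zm00001d005587	five_prime_UTR	10	60	81	122
Zm00001d023962	five_prime_UTR	78	488	181	463
Zm00001d008642	five_prime_UTR	119	1235	361	1782
Zm00001d006126	intron	83	68	144	50
Zm00001d006768	promoter	63	93	79	62
Zm00001d033167	promoter	154	69	140	112
Zm00001d039683	promoter	206	95	166	86
Zm00001d012812	promoter	752	405	239	138
Zm00001d039156	five_prime_UTR	455	838	542	676
Zm00001d047761	five_prime_UTR	161	393	50	83
Zm00001d018461	five_prime_UTR	402	818	223	383
Zm00001d022153	five_prime_UTR	320	208	122	79
Zm00001d034667	five_prime_UTR	924	854	288	302
Zm00001d034191	five_prime_UTR	138	96	36	30
Zm00001d028784	five_prime_UTR	27	20	355	349
Zm00001d050081	five_prime_UTR	53	53	31	42
Zm00001d039253	five_prime_UTR	30	184	16	133
Zm00001d001788	five_prime_UTR	233	178	497	563
Zm00001d029856	intron	189	314	104	96
Zm00001d050163	intron	8	11	127	110
Zm00001d053452	intron	963	1324	236	310
Zm00001d049619	intron	70	260	251	1275
Zm00001d006610	three_prime_UTR	336	292	288	232
Zm00001d029059	five_prime_UTR	244	131	46	59
Zm00001d022122	intron	43	29	2	9
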