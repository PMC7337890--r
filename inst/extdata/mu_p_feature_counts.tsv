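dataset	total	category	count
Random_Zm	421280	genic	32246
Random_Zm	421280	up500	3985
Random_Zm	421280	up200	1544
Random_Zm	421280	utr5	1268
Random_Zm	421280	cds	9188
Random_Zm	421280	utr3	1889
Random_Zm	421280	down200	1508
Random_Zm	421280	down500	3781
UniformMu_Zm	92702	genic	54040
UniformMu_Zm	92702	up500	15976
UniformMu_Zm	92702	up200	12103
UniformMu_Zm	92702	utr5	25142
UniformMu_Zm	92702	cds	14220
UniformMu_Zm	92702	utr3	1471
UniformMu_Zm	92702	down200	1220
UniformMu_Zm	92702	down500	2703
SomaticMu_Zm	320044	genic	181776
SomaticMu_Zm	320044	up500	45582
SomaticMu_Zm	320044	up200	32739
SomaticMu_Zm	320044	utr5	62028
SomaticMu_Zm	320044	cds	61393
SomaticMu_Zm	320044	utr3	7046
SomaticMu_Zm	320044	down200	5760
SomaticMu_Zm	320044	down500	12279
Pack_MULE_Zm	1369	genic	183
Pack_MULE_Zm	1369	up500	167
Pack_MULE_Zm	1369	up200	94
Pack_MULE_Zm	1369	utr5	20
Pack_MULE_Zm	1369	cds	17
Pack_MULE_Zm	1369	utr3	25
Pack_MULE_Zm	1369	down200	16
Pack_MULE_Zm	1369	down500	52
Random_Dm	349280	genic	222916
Random_Dm	349280	up500	13746
Random_Dm	349280	up200	6511
Random_Dm	349280	utr5	11315
Random_Dm	349280	cds	56979
Random_Dm	349280	utr3	18468
Random_Dm	349280	down200	5498
Random_Dm	349280	down500	10968
P_Dm	18213	genic	12586
P_Dm	18213	up500	5485
P_Dm	18213	up200	4409
P_Dm	18213	utr5	4578
P_Dm	18213	cds	729
P_Dm	18213	utr3	264
P_Dm	18213	down200	333
P_Dm	18213	down500	967
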