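receptor	mutation	bw	category	activity	activity_fold_wt	source_table
FSHR	M401T	2.43	CAM	cAMP 3.60-fold WT	3.60	2
FSHR	T449A	3.32	CAM	cAMP 2.5-fold WT	2.5	2
FSHR	L460R	3.43	CAM	cAMP 5-fold WT	5	2
FSHR	I545T	5.46	CAM	cAMP 2.3-fold WT	2.3	2
FSHR	I545L	5.46	CAM	cAMP 4.53-fold WT	4.53	2
FSHR	D567N	6.30	CAM	cAMP 3-fold WT	3	2
FSHR	M574I	6.37	CAM	cAMP 2.19-fold WT	2.19	2
FSHR	A575V	6.38	CAM	cAMP 2.95-fold WT	2.95	2
FSHR	I578L	6.41	CAM	cAMP 2.49-fold WT	2.49	2
FSHR	T580I	6.43	CAM	cAMP 5.41-fold WT	5.41	2
LHR	A373V	1.46	CAM	cAMP 7.5-fold WT	7.5	3
LHR	M398T	2.43	CAM	cAMP 25-fold WT	25	3
LHR	L457R	3.43	CAM	cAMP 10-fold WT	10	3
LHR	I542L	5.55	CAM	cAMP 7-fold WT	7	3
LHR	D564G	6.30	CAM	cAMP 5-fold WT	5	3
LHR	A568V	6.34	CAM	cAMP 4-fold WT	4	3
LHR	M571I	6.37	activating		NA	3
LHR	A572V	6.38	activating		NA	3
LHR	I575L	6.41	CAM	cAMP 20-fold WT	20	3
LHR	T577I	6.43	activating		NA	3
LHR	D578G	6.44	CAM	cAMP 6.6-fold WT	6.6	3
LHR	D578Y	6.44	CAM	cAMP 13-fold WT	13	3
LHR	D578E	6.44	CAM	cAMP 4.3-fold WT	4.3	3
LHR	D578H	6.44	CAM	cAMP 14.4-fold WT	14.4	3
LHR	D578Q	6.44	CAM	cAMP 10.2-fold WT	10.2	3
LHR	C581R	6.47	CAM	cAMP 5-fold WT	5	3
LHR	N615R	7.45	CAM	cAMP 2.6-fold WT	2.6	3
TSHR	V421I	1.39	CAM	cAMP 2.1-fold WT	2.1	4
TSHR	Y466A	2.56	CAM	cAMP 2.8-fold WT	2.8	4
TSHR	I486N	ECL1	CAM	cAMP 4-fold WT	4	4
TSHR	T501A	3.32	CAM	cAMP 3.4-fold WT	3.4	4
TSHR	L512R	3.43	CAM	cAMP 3.2-fold WT	3.2	4
TSHR	A593G	5.50	CAM	cAMP 2.13-fold WT	2.13	4
TSHR	L629F	6.40	CAM	cAMP 2.2-fold WT	2.2	4
TSHR	F631I	6.42	CAM	cAMP 3.7-fold WT	3.7	4
TSHR	T632A	6.43	CAM	cAMP 9.7-fold WT	9.7	4
TSHR	D633A	6.44	CAM	cAMP 13.6-fold WT	13.6	4
TSHR	D633E	6.44	CAM	cAMP 3.3-fold WT	3.3	4
TSHR	C636R	6.47	CAM	cAMP 7.7-fold WT	7.7	4
TSHR	C636S	6.47	CAM	cAMP 5.5-fold WT	5.5	4
TSHR	M637C	6.48	CAM	cAMP 2.4-fold WT	2.4	4
TSHR	M637W	6.48	CAM	cAMP 4.8-fold WT	4.8	4
TSHR	P639G	6.50	CAM	cAMP 4.9-fold WT	4.9	4
TSHR	P639A	6.50	CAM	cAMP 4.8-fold WT	4.8	4
TSHR	P639S	6.50	CAM	cAMP 4.8-fold WT	4.8	4
TSHR	S641A	6.52	CAM	cAMP 3.1-fold WT	3.1	4
TSHR	Y643F	6.54	CAM	cAMP 2.1-fold WT	2.1	4
TSHR	L645V	6.56	CAM	cAMP 2.1-fold WT	2.1	4
TSHR	L665F	7.40	CAM	cAMP 3-fold WT	3	4
TSHR	N674D	7.49	CAM	cAMP 11.3-fold WT	11.3	4
FSHR	I418S	2.60	inactivating	FSH-induced cAMP abolished	NA	5
FSHR	A419T	2.61	inactivating	FSH-induced cAMP abolished	NA	5
FSHR	P519T	ECL2	inactivating	FSH-induced cAMP abolished	NA	5
FSHR	R573C	6.36	inactivating	FSH-induced max. cAMP 30% WT	NA	5
FSHR	A575V	6.38	inactivating	FSH-induced cAMP abolished	NA	5
FSHR	P587H	6.50	inactivating	FSH-induced cAMP abolished	NA	5
FSHR	L601V	ECL3	inactivating	FSH-induced max. cAMP 20% WT	NA	5
LHR	I374T	1.47	inactivating		NA	6
LHR	T392I	ICL1	inactivating		NA	6
LHR	C543R	5.55	inactivating	LH-induced cAMP abolished	NA	6
LHR	A593P	6.59	inactivating	LH-induced cAMP abolished	NA	6
LHR	S616Y	7.46	inactivating	LH-induced EC50 20-fold WT	NA	6
LHR	I625K	7.55	inactivating	LH-induced EC50 20-fold WT	NA	6
TSHR	V424I	1.42	silencing	cAMP 0.3-fold WT	0.3	7
TSHR	D460A	2.50	silencing	cAMP 0.28-fold WT	0.28	7
TSHR	D460N	2.50	silencing	cAMP 0.18-fold WT	0.18	7
TSHR	L467V	2.57	silencing	cAMP 0.1-fold WT	0.1	7
TSHR	W488R	ECL1	inactivating	TSH binding abolished	NA	7
TSHR	V502A	3.33	silencing	cAMP 0.0-fold WT	0.0	7
TSHR	M527T	ICL2	inactivating	TSH induced max. cAMP 30% WT	NA	7
TSHR	Y582A	5.39	silencing	cAMP 0.2-fold WT	0.2	7
TSHR	Y582F	5.39	silencing	cAMP 0.4-fold WT	0.4	7
TSHR	A593P	5.50	silencing	cAMP 0.19-fold WT	0.19	7
TSHR	A593V	5.50	silencing	cAMP 0.33-fold WT	0.33	7
TSHR	F594I	5.51	silencing	cAMP 0.13-fold WT	0.13	7
TSHR	R625A	6.36	silencing	cAMP 0.11-fold WT	0.11	7
TSHR	F634I	6.45	silencing	cAMP 0.13-fold WT	0.13	7
TSHR	A638V	6.49	inactivating	TSH induced EC50 7.85-fold WT	NA	7
TSHR	F642I	6.53	inactivating	TSH induced EC50 8.21-fold WT	NA	7
TSHR	Y643A	6.54	silencing	cAMP 0.2-fold WT	0.2	7
TSHR	A644V	6.55	inactivating	TSH induced EC50 8.88-fold WT	NA	7
TSHR	L665V	7.40	silencing	cAMP 0.3-fold WT	0.3	7
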