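pt	soc	a	b	c	d	ror	ror_low	ror_high	prr	chi2	ebgm	ebgm05
Headache	Nervous system disorders	15	457	10840	1259929	3.81	2.28	6.38	3.73	30.12	3.72	2.42
Dyspnoea	Respiratory, thoracic and mediastinal disorders	14	458	5651	1265118	6.84	4.02	11.65	6.67	67.61	6.66	4.26
Rash	Skin and subcutaneous tissue disorders	11	461	13076	1257693	2.3	1.26	4.17	2.26	7.84	2.26	1.37
Wheezing	Respiratory, thoracic and mediastinal disorders	8	464	931	1269838	23.52	11.66	47.44	23.13	168.1	22.95	12.75
Back pain	Musculoskeletal and connective tissue disorders	7	465	1719	1269050	11.11	5.26	23.48	10.96	63.21	10.92	5.84
Exposure via skin contact	Injury, poisoning and procedural complications	7	465	510	1270259	37.49	17.69	79.49	36.95	241.65	36.47	19.45
Fatigue	General disorders and administration site conditions	6	466	6890	1263879	2.36	1.06	5.29	2.34	4.65	2.34	1.19
Chest discomfort	General disorders and administration site conditions	5	467	1047	1269722	12.98	5.37	31.41	12.86	54.46	12.8	6.11
Cough	Respiratory, thoracic and mediastinal disorders	5	467	5390	1265379	2.51	1.04	6.07	2.5	4.5	2.5	1.19
Urticaria	Skin and subcutaneous tissue disorders	5	467	5589	1265180	2.42	1	5.85	2.41	4.13	2.41	1.15
Therapy non-responder	General disorders and administration site conditions	5	467	1503	1269266	9.04	3.74	21.86	8.96	35.27	8.93	4.27
Eczema	Skin and subcutaneous tissue disorders	4	468	2665	1268104	4.07	1.52	10.89	4.04	9.16	4.04	1.77
Therapeutic response unexpected	General disorders and administration site conditions	3	469	651	1270118	12.48	4	38.94	12.41	31.33	12.35	4.77
Therapeutic product effect decreased	General disorders and administration site conditions	3	469	1279	1269490	6.35	2.04	19.78	6.32	13.4	6.3	2.44
Migraine	Nervous system disorders	3	469	1058	1269711	7.68	2.46	23.93	7.63	17.26	7.62	2.94
Bronchospasm	Respiratory, thoracic and mediastinal disorders	3	469	531	1270238	15.3	4.9	47.77	15.21	39.62	15.13	5.84
Treatment non-compliance	General disorders and administration site conditions	3	469	1646	1269123	4.93	1.58	15.36	4.91	9.33	4.9	1.89
Angioedema	Skin and subcutaneous tissue disorders	3	469	1291	1269478	6.29	2.02	19.6	6.26	13.23	6.24	2.41
Injection site erythema	General disorders and administration site conditions	3	469	1750	1269019	4.64	1.49	14.45	4.62	8.49	4.61	1.78
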