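term	a	b	c	d	ror	ror_low	ror_high	prr	chi2	ebgm	ebgm05
Musculoskeletal and connective tissue disorders	18	454	31125	1239644	1.58	0.99	2.53	1.56	3.67	1.56	1.05
General disorders and administration site conditions	89	383	170996	1099773	1.49	1.19	1.88	1.4	11.81	1.4	1.16
Nervous system disorders	31	441	95225	1175544	0.87	0.6	1.25	0.88	0.58	0.88	0.65
Gastrointestinal disorders	21	451	87685	1183084	0.63	0.41	0.97	0.64	4.41	0.64	0.45
Vascular disorders	3	469	20690	1250079	0.39	0.12	1.2	0.39	2.9	0.39	0.15
Respiratory, thoracic and mediastinal disorders	84	388	50061	1220708	5.28	4.17	6.68	4.52	239.12	4.51	3.70
Injury, poisoning and procedural complications	92	380	205319	1065450	1.26	1	1.58	1.21	3.87	1.21	1
Psychiatric disorders	10	462	82293	1188476	0.31	0.17	0.58	0.33	14.79	0.33	0.19
Infections and infestations	22	450	74848	1195921	0.78	0.51	1.2	0.79	1.29	0.79	0.55
Skin and subcutaneous tissue disorders	36	436	145798	1124971	0.64	0.45	0.9	0.66	6.87	0.66	0.5
Neoplasms benign, malignant and unspecified (incl cysts and polyps)	1	471	11140	1259629	0.24	0.03	1.71	0.24	2.4	0.24	0.05
Immune system disorders	8	464	18952	1251817	1.14	0.57	2.29	1.14	0.13	1.14	0.63
Investigations	13	459	66326	1204443	0.51	0.3	0.89	0.53	5.8	0.53	0.33
Surgical and medical procedures	4	468	11034	1259735	0.98	0.36	2.61	0.98	0	0.98	0.43
Blood and lymphatic system disorders	5	467	31300	1239469	0.42	0.18	1.02	0.43	3.87	0.43	0.21
Ear and labyrinth disorders	4	468	3148	1267621	3.44	1.29	9.21	3.42	6.86	3.42	1.5
Renal and urinary disorders	2	470	15864	1254905	0.34	0.08	1.35	0.34	2.6	0.34	0.11
Eye disorders	12	460	21074	1249695	1.55	0.87	2.74	1.53	2.26	1.53	0.95
Cardiac disorders	2	470	20573	1250196	0.26	0.06	1.04	0.26	4.23	0.26	0.08
Metabolism and nutrition disorders	1	471	26403	1244366	0.1	0.01	0.71	0.1	8.08	0.1	0.02
Social circumstances	2	470	3515	1267254	1.53	0.38	6.15	1.53	0.37	1.53	0.48
Reproductive system and breast disorders	1	471	15498	1255271	0.17	0.02	1.22	0.17	3.98	0.17	0.03
Product issues	9	463	38664	1232105	0.62	0.32	1.2	0.63	2.06	0.63	0.36
Endocrine disorders	1	471	4414	1266355	0.61	0.09	4.33	0.61	0.25	0.61	0.12
Hepatobiliary disorders	1	471	11995	1258774	0.22	0.03	1.59	0.22	2.71	0.22	0.04
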