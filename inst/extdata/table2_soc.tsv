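term	a	b	c	d	ror	ror_low	ror_high	prr	chi2	ebgm	ebgm05
Respiratory, thoracic and mediastinal disorders	16136	66342	1623032	34149902	5.12	5.03	5.21	4.31	42592.6	4.28	4.22
Social circumstances	900	81578	161743	35611191	2.43	2.27	2.59	2.41	744.25	2.41	2.28
Surgical and medical procedures	2712	79766	498195	35274739	2.41	2.32	2.5	2.36	2146.29	2.35	2.28
Infections and infestations	7995	74483	1955341	33817593	1.86	1.81	1.9	1.77	2841.35	1.77	1.74
Injury, poisoning and procedural complications	12568	69910	4208192	31564742	1.35	1.32	1.37	1.3	956.42	1.29	1.27
Immune system disorders	1136	81342	432311	35340623	1.14	1.08	1.21	1.14	19.64	1.14	1.08
General disorders and administration site conditions	14257	68221	6371543	29401391	0.96	0.95	0.98	0.97	15.51	0.97	0.96
Product issues	1287	81191	630502	35142432	0.88	0.84	0.93	0.89	19.42	0.89	0.85
Musculoskeletal and connective tissue disorders	3757	78721	1858061	33914873	0.87	0.84	0.9	0.88	68.23	0.88	0.85
Ear and labyrinth disorders	308	82170	156321	35616613	0.85	0.76	0.96	0.85	7.64	0.85	0.78
Cardiac disorders	1222	81256	729526	35043408	0.72	0.68	0.76	0.73	128.2	0.73	0.69
Investigations	3270	79208	2084922	33688012	0.67	0.64	0.69	0.68	521.01	0.68	0.66
Endocrine disorders	145	82333	94104	35678830	0.67	0.57	0.79	0.67	23.9	0.67	0.58
Nervous system disorders	4304	78174	2773592	32999342	0.66	0.64	0.68	0.67	739.85	0.67	0.66
Skin and subcutaneous tissue disorders	2925	79553	2035958	33736976	0.61	0.59	0.63	0.62	705.92	0.62	0.6
Eye disorders	989	81489	694944	35077990	0.61	0.58	0.65	0.62	239.03	0.62	0.59
Vascular disorders	957	81521	687041	35085893	0.6	0.56	0.64	0.6	252.72	0.6	0.57
Metabolism and nutrition disorders	684	81794	723365	35049569	0.41	0.38	0.44	0.41	591.71	0.41	0.39
Gastrointestinal disorders	2892	79586	2966487	32806447	0.4	0.39	0.42	0.42	2481.67	0.42	0.41
Psychiatric disorders	1751	80727	1909836	33863098	0.38	0.37	0.4	0.4	1686.03	0.4	0.38
Renal and urinary disorders	578	81900	698752	35074182	0.35	0.33	0.38	0.36	675.03	0.36	0.34
Neoplasms benign, malignant and unspecified (incl cysts and polyps)	865	81613	1095325	34677609	0.34	0.31	0.36	0.34	1125.2	0.34	0.32
Hepatobiliary disorders	217	82261	291581	35481353	0.32	0.28	0.37	0.32	310.61	0.32	0.29
Congenital, familial and genetic disorders	74	82404	99726	35673208	0.32	0.26	0.4	0.32	105.96	0.32	0.27
Reproductive system and breast disorders	176	82302	268293	35504641	0.28	0.24	0.33	0.28	318.83	0.28	0.25
Blood and lymphatic system disorders	321	82157	586024	35186910	0.23	0.21	0.26	0.24	798.02	0.24	0.22
Pregnancy, puerperium and perinatal conditions	52	82426	138054	35634880	0.16	0.12	0.21	0.16	223.57	0.16	0.13
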