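pt	soc	a	b	c	d	ror	ror_low	ror_high	prr	chi2	ebgm	ebgm05
Diabetes mellitus	Metabolism and nutrition disorders	135	82343	36962	35735972	1.59	1.34	1.88	1.58	29	1.58	1.37
Coronavirus infection	Infections and infestations	107	82371	6338	35766596	7.33	6.05	8.88	7.32	574.51	7.22	6.15
Pneumonia	Infections and infestations	2141	80337	193520	35579414	4.9	4.69	5.12	4.8	6402.3	4.76	4.59
Respiratory tract infection	Infections and infestations	173	82305	15632	35757302	4.81	4.14	5.59	4.8	514.98	4.76	4.2
Lower respiratory tract infection	Infections and infestations	252	82226	28639	35744295	3.83	3.38	4.33	3.82	519.62	3.79	3.42
Herpes zoster	Infections and infestations	299	82179	34811	35738123	3.74	3.33	4.19	3.73	591.65	3.7	3.37
Influenza	Infections and infestations	450	82028	68755	35704179	2.85	2.6	3.13	2.84	533.5	2.83	2.62
Bronchitis	Infections and infestations	283	82195	42388	35730546	2.9	2.58	3.26	2.9	349.31	2.88	2.61
Sinusitis	Infections and infestations	357	82121	61159	35711775	2.54	2.29	2.82	2.53	329.5	2.52	2.31
Nasopharyngitis	Infections and infestations	538	81940	113561	35659373	2.06	1.89	2.24	2.05	290.86	2.05	1.91
Cellulitis	Infections and infestations	130	82348	28568	35744366	1.98	1.66	2.35	1.97	62.21	1.97	1.7
COVID-19	Infections and infestations	483	81995	156089	35616845	1.34	1.23	1.47	1.34	42.18	1.34	1.24
Infection	Infections and infestations	262	82216	86317	35686617	1.32	1.17	1.49	1.32	19.92	1.32	1.19
Eosinophil count increased	Investigations	103	82375	4840	35768094	9.24	7.6	11.23	9.23	740.22	9.06	7.69
Full blood count abnormal	Investigations	183	82295	19886	35753048	4	3.46	4.63	3.99	406.75	3.96	3.51
Oxygen saturation decreased	Investigations	227	82251	33772	35739162	2.92	2.56	3.33	2.92	284	2.9	2.6
Heart rate increased	Investigations	206	82272	53150	35719784	1.68	1.47	1.93	1.68	56.7	1.68	1.5
Blood pressure increased	Investigations	303	82175	90291	35682643	1.46	1.3	1.63	1.46	43.16	1.45	1.32
Headache	Nervous system disorders	1141	81337	361852	35411082	1.37	1.29	1.46	1.37	113.56	1.37	1.3
Back pain	Musculoskeletal and connective tissue disorders	708	81770	133099	35639835	2.32	2.15	2.5	2.31	523.51	2.3	2.16
Myalgia	Musculoskeletal and connective tissue disorders	276	82202	90819	35682115	1.32	1.17	1.48	1.32	21.18	1.32	1.19
Asthmatic crisis	Respiratory, thoracic and mediastinal disorders	522	81956	2172	35770762	104.9	95.31	115.44	104.24	43034.77	84.23	77.75
Sputum discolored	Respiratory, thoracic and mediastinal disorders	261	82217	6213	35766721	18.27	16.14	20.69	18.22	4077.31	17.53	15.8
Wheezing	Respiratory, thoracic and mediastinal disorders	1242	81236	33472	35739462	16.32	15.42	17.28	16.09	16968.96	15.55	14.83
Productive cough	Respiratory, thoracic and mediastinal disorders	559	81919	29433	35743501	8.29	7.62	9.01	8.24	3491.27	8.1	7.55
Obstructive airways disorder	Respiratory, thoracic and mediastinal disorders	151	82327	7624	35765310	8.6	7.32	10.11	8.59	993.27	8.44	7.38
Pulmonary congestion	Respiratory, thoracic and mediastinal disorders	121	82357	6303	35766631	8.34	6.96	9.98	8.33	765.47	8.19	7.04
Bronchospasm	Respiratory, thoracic and mediastinal disorders	104	82374	6892	35766042	6.55	5.4	7.95	6.54	481.39	6.46	5.5
Dyspnoea exertional	Respiratory, thoracic and mediastinal disorders	280	82198	22786	35750148	5.34	4.75	6.01	5.33	973.53	5.28	4.78
Dyspnoea	Respiratory, thoracic and mediastinal disorders	3185	79293	313136	35459798	4.55	4.39	4.71	4.41	8392.24	4.38	4.25
Cough	Respiratory, thoracic and mediastinal disorders	1688	80790	168314	35604620	4.42	4.21	4.64	4.35	4331.82	4.32	4.15
Respiratory disorder	Respiratory, thoracic and mediastinal disorders	164	82314	15928	35757006	4.47	3.83	5.22	4.47	436.81	4.43	3.89
Nasal congestion	Respiratory, thoracic and mediastinal disorders	314	82164	34452	35738482	3.96	3.55	4.43	3.95	687.1	3.93	3.58
Chronic obstructive pulmonary disease	Respiratory, thoracic and mediastinal disorders	253	82225	27682	35745252	3.97	3.51	4.5	3.96	556.08	3.94	3.55
Lung disorder	Respiratory, thoracic and mediastinal disorders	237	82241	27666	35745268	3.72	3.28	4.23	3.72	466.73	3.69	3.32
Rhinorrhoea	Respiratory, thoracic and mediastinal disorders	221	82257	40498	35732436	2.37	2.08	2.71	2.37	173.7	2.36	2.11
Dysphonia	Respiratory, thoracic and mediastinal disorders	188	82290	34258	35738676	2.38	2.06	2.75	2.38	149.78	2.37	2.1
Oropharyngeal pain	Respiratory, thoracic and mediastinal disorders	254	82224	56234	35716700	1.96	1.73	2.22	1.96	118.91	1.95	1.76
Sleep disorder due to a general medical condition	Psychiatric disorders	311	82167	7772	35765162	17.42	15.55	19.51	17.36	4610.17	16.73	15.21
Anaphylactic reaction	Immune system disorders	152	82326	29474	35743460	2.24	1.91	2.63	2.24	103.5	2.23	1.95
Hypersensitivity	Immune system disorders	300	82178	110697	35662237	1.18	1.05	1.32	1.18	7.86	1.17	1.07
Urticaria	Skin and subcutaneous tissue disorders	306	82172	90597	35682337	1.47	1.31	1.64	1.46	45.12	1.46	1.33
Secretion discharge	General disorders and administration site conditions	140	82338	7983	35764951	7.62	6.44	9	7.61	789.63	7.49	6.51
Chest discomfort	General disorders and administration site conditions	486	81992	54946	35717988	3.85	3.52	4.21	3.84	1011.77	3.81	3.54
Therapeutic product effect incomplete	General disorders and administration site conditions	552	81926	85511	35687423	2.81	2.59	3.06	2.8	636.1	2.79	2.6
Ill-defined disorder	General disorders and administration site conditions	241	82237	42202	35730732	2.48	2.19	2.82	2.48	211.27	2.47	2.22
Illness	General disorders and administration site conditions	333	82145	66341	35706593	2.18	1.96	2.43	2.18	211.26	2.17	1.98
Therapeutic response unexpected	General disorders and administration site conditions	144	82334	29367	35743567	2.13	1.81	2.51	2.13	85.61	2.12	1.85
Condition aggravated	General disorders and administration site conditions	843	81635	192677	35580257	1.91	1.78	2.04	1.9	358.32	1.89	1.79
Malaise	General disorders and administration site conditions	1099	81379	264616	35508318	1.81	1.71	1.92	1.8	393.07	1.8	1.71
Influenza like illness	General disorders and administration site conditions	175	82303	41475	35731459	1.83	1.58	2.13	1.83	65.69	1.83	1.61
Chest pain	General disorders and administration site conditions	312	82166	89408	35683526	1.52	1.36	1.69	1.51	54.31	1.51	1.38
Injection site pain	General disorders and administration site conditions	502	81976	155982	35616952	1.4	1.28	1.53	1.4	56.43	1.39	1.3
Pyrexia	General disorders and administration site conditions	589	81889	190844	35582090	1.34	1.24	1.45	1.34	50.56	1.34	1.25
Fatigue	General disorders and administration site conditions	1279	81199	478883	35294051	1.16	1.1	1.23	1.16	28	1.16	1.11
Swelling face	General disorders and administration site conditions	105	82373	34199	35738735	1.33	1.1	1.61	1.33	8.65	1.33	1.13
Discomfort	General disorders and administration site conditions	107	82371	38116	35734818	1.22	1.01	1.47	1.22	4.15	1.22	1.04
Cardiac disorder	Cardiac disorders	133	82345	46857	35726077	1.23	1.04	1.46	1.23	5.76	1.23	1.07
Cataract	Eye disorders	172	82306	34004	35738930	2.2	1.89	2.55	2.19	111.29	2.19	1.93
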