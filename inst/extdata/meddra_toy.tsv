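# Toy PT->SOC dictionary bundled with pvsignal.
# Primary-SOC-only stand-in for a licensed MedDRA release; covers the
# preferred terms used by the synthetic generator and validation tables.
version: 26.0-toy
Cardiac disorder	Cardiac disorders
Cataract	Eye disorders
Chest discomfort	General disorders and administration site conditions
Chest pain	General disorders and administration site conditions
Condition aggravated	General disorders and administration site conditions
Discomfort	General disorders and administration site conditions
Fatigue	General disorders and administration site conditions
Ill-defined disorder	General disorders and administration site conditions
Illness	General disorders and administration site conditions
Influenza like illness	General disorders and administration site conditions
Injection site erythema	General disorders and administration site conditions
Injection site pain	General disorders and administration site conditions
Malaise	General disorders and administration site conditions
Pyrexia	General disorders and administration site conditions
Secretion discharge	General disorders and administration site conditions
Swelling face	General disorders and administration site conditions
Therapeutic product effect decreased	General disorders and administration site conditions
Therapeutic product effect incomplete	General disorders and administration site conditions
Therapeutic response unexpected	General disorders and administration site conditions
Therapy non-responder	General disorders and administration site conditions
Treatment non-compliance	General disorders and administration site conditions
Anaphylactic reaction	Immune system disorders
Hypersensitivity	Immune system disorders
Bronchitis	Infections and infestations
Cellulitis	Infections and infestations
Coronavirus infection	Infections and infestations
COVID-19	Infections and infestations
Herpes zoster	Infections and infestations
Infection	Infections and infestations
Influenza	Infections and infestations
Lower respiratory tract infection	Infections and infestations
Nasopharyngitis	Infections and infestations
Pneumonia	Infections and infestations
Respiratory tract infection	Infections and infestations
Sinusitis	Infections and infestations
Exposure via skin contact	Injury, poisoning and procedural complications
Blood pressure increased	Investigations
Eosinophil count increased	Investigations
Full blood count abnormal	Investigations
Heart rate increased	Investigations
Oxygen saturation decreased	Investigations
Diabetes mellitus	Metabolism and nutrition disorders
Back pain	Musculoskeletal and connective tissue disorders
Myalgia	Musculoskeletal and connective tissue disorders
Headache	Nervous system disorders
Migraine	Nervous system disorders
Sleep disorder due to a general medical condition	Psychiatric disorders
Asthmatic crisis	Respiratory, thoracic and mediastinal disorders
Bronchospasm	Respiratory, thoracic and mediastinal disorders
Chronic obstructive pulmonary disease	Respiratory, thoracic and mediastinal disorders
Cough	Respiratory, thoracic and mediastinal disorders
Dysphonia	Respiratory, thoracic and mediastinal disorders
Dyspnoea	Respiratory, thoracic and mediastinal disorders
Dyspnoea exertional	Respiratory, thoracic and mediastinal disorders
Lung disorder	Respiratory, thoracic and mediastinal disorders
Nasal congestion	Respiratory, thoracic and mediastinal disorders
Obstructive airways disorder	Respiratory, thoracic and mediastinal disorders
Oropharyngeal pain	Respiratory, thoracic and mediastinal disorders
Productive cough	Respiratory, thoracic and mediastinal disorders
Pulmonary congestion	Respiratory, thoracic and mediastinal disorders
Respiratory disorder	Respiratory, thoracic and mediastinal disorders
Rhinorrhoea	Respiratory, thoracic and mediastinal disorders
Sputum discolored	Respiratory, thoracic and mediastinal disorders
Wheezing	Respiratory, thoracic and mediastinal disorders
Angioedema	Skin and subcutaneous tissue disorders
Eczema	Skin and subcutaneous tissue disorders
Rash	Skin and subcutaneous tissue disorders
Urticaria	Skin and subcutaneous tissue disorders
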