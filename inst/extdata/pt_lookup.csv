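pt,soc,hlt,excluded_class,renal_indication
Thrombocytopenia,Blood and lymphatic system disorders,,,0
Pancytopenia,Blood and lymphatic system disorders,,,0
Febrile neutropenia,Blood and lymphatic system disorders,,,0
Neutropenia,Blood and lymphatic system disorders,,,0
Anaemia,Blood and lymphatic system disorders,,,0
Transaminases increased,Investigations,,,0
Blood creatinine increased,Investigations,,,0
Hepatotoxicity,Hepatobiliary disorders,,,0
Hepatic failure,Hepatobiliary disorders,,,0
Toxic epidermal necrolysis,Skin and subcutaneous tissue disorders,,,0
Erythrodermic psoriasis,Skin and subcutaneous tissue disorders,,,0
Rash,Skin and subcutaneous tissue disorders,,,0
Alopecia,Skin and subcutaneous tissue disorders,,,0
Stomatitis,Gastrointestinal disorders,,,0
Mucosal inflammation,Gastrointestinal disorders,,,0
Nausea,Gastrointestinal disorders,,,0
Vomiting,Gastrointestinal disorders,,,0
Diarrhoea,Gastrointestinal disorders,,,0
Rheumatoid lung,"Respiratory, thoracic and mediastinal disorders",,,0
Pulmonary toxicity,"Respiratory, thoracic and mediastinal disorders",,,0
Pneumonitis,"Respiratory, thoracic and mediastinal disorders",,,0
Hand deformity,Musculoskeletal and connective tissue disorders,,,0
Tenosynovitis,Musculoskeletal and connective tissue disorders,,,0
Synovitis,Musculoskeletal and connective tissue disorders,,,0
Arthralgia,Musculoskeletal and connective tissue disorders,,,0
Fatigue,General disorders and administration site conditions,,,0
Pyrexia,General disorders and administration site conditions,,,0
Drug ineffective,General disorders and administration site conditions,,,0
Headache,Nervous system disorders,,,0
Dizziness,Nervous system disorders,,,0
Pneumonia,Infections and infestations,,,0
Sepsis,Infections and infestations,,,0
Euphoric mood,Psychiatric disorders,,,0
B-cell lymphoma,"Neoplasms benign, malignant and unspecified (incl cysts and polyps)",,,0
Dry eye,Eye disorders,,,0
Product quality issue,Product issues,,product issues,0
Fall,"Injury, poisoning and procedural complications",,injuries,0
Overdose,"Injury, poisoning and procedural complications",,poisoning,0
Medication error,"Injury, poisoning and procedural complications",,medication errors,0
Post procedural complication,"Injury, poisoning and procedural complications",,surgical complications,0
Surgical procedure,Surgical and medical procedures,,medical procedures,0
Economic problem,Social circumstances,,social environment,0
Renal failure,Renal and urinary disorders,Renal failure and impairment,,1
Renal impairment,Renal and urinary disorders,Renal failure and impairment,,1
Chronic kidney disease,Renal and urinary disorders,Renal failure and impairment,,1
Acute kidney injury,Renal and urinary disorders,Renal failure and impairment,,1
Azotaemia,Renal and urinary disorders,Complications of renal failure,,1
Uraemia,Renal and urinary disorders,Complications of renal failure,,1
Rheumatoid arthritis,Musculoskeletal and connective tissue disorders,,,0
Psoriasis,Skin and subcutaneous tissue disorders,,,0
Psoriatic arthropathy,Musculoskeletal and connective tissue disorders,,,0
Crohn's disease,Gastrointestinal disorders,,,0
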