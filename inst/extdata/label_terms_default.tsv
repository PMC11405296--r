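drug	pt
ide-cel	Cytokine release syndrome
ide-cel	Immune effector cell-associated neurotoxicity syndrome
ide-cel	Neurotoxicity
ide-cel	Febrile neutropenia
ide-cel	Neutropenia
ide-cel	Thrombocytopenia
ide-cel	Anaemia
ide-cel	Leukopenia
ide-cel	Lymphopenia
ide-cel	Hypogammaglobulinaemia
ide-cel	Infection
ide-cel	Pneumonia
ide-cel	Sepsis
ide-cel	Fatigue
ide-cel	Pyrexia
ide-cel	Hypotension
ide-cel	Tachycardia
ide-cel	Headache
ide-cel	Encephalopathy
ide-cel	Tremor
ide-cel	Hypoxia
ide-cel	Diarrhoea
ide-cel	Nausea
ide-cel	Oedema peripheral
cilta-cel	Cytokine release syndrome
cilta-cel	Immune effector cell-associated neurotoxicity syndrome
cilta-cel	Neurotoxicity
cilta-cel	Parkinsonism
cilta-cel	Guillain-Barre syndrome
cilta-cel	Cranial nerve paralysis
cilta-cel	Facial paralysis
cilta-cel	Bell's palsy
cilta-cel	Febrile neutropenia
cilta-cel	Neutropenia
cilta-cel	Thrombocytopenia
cilta-cel	Anaemia
cilta-cel	Leukopenia
cilta-cel	Lymphopenia
cilta-cel	Hypogammaglobulinaemia
cilta-cel	Infection
cilta-cel	Pneumonia
cilta-cel	Sepsis
cilta-cel	Fatigue
cilta-cel	Pyrexia
cilta-cel	Hypotension
cilta-cel	Headache
cilta-cel	Encephalopathy
cilta-cel	Haemophagocytic lymphohistiocytosis
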