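group	pt
Leukaemias	Acute myeloid leukaemia
Leukaemias	Chronic lymphocytic leukaemia
Leukaemias	T-cell lymphoblastic leukaemia
Leukaemias	Leukaemia
Plasma cell neoplasms	Plasma cell myeloma
Plasma cell neoplasms	Plasma cell myeloma recurrent
Plasma cell neoplasms	Plasmacytoma
Skin neoplasms malignant and unspecified	Squamous cell carcinoma of skin
Skin neoplasms malignant and unspecified	Basal cell carcinoma
Skin neoplasms malignant and unspecified	Malignant melanoma
Skin neoplasms malignant and unspecified	Bowen's disease
Lymphomas non-Hodgkin's unspecified histology	Non-Hodgkin's lymphoma
Lymphomas non-Hodgkin's unspecified histology	B-cell lymphoma
Lymphomas non-Hodgkin's T-cell	T-cell lymphoma
Lymphomas non-Hodgkin's T-cell	Peripheral T-cell lymphoma unspecified
Gastrointestinal neoplasms malignant and unspecified	Colon cancer
Gastrointestinal neoplasms malignant and unspecified	Gastric cancer
Gastrointestinal neoplasms malignant and unspecified	Pancreatic carcinoma
Miscellaneous and site unspecified neoplasms malignant and unspecified	Myelodysplastic syndrome
Miscellaneous and site unspecified neoplasms malignant and unspecified	Metastatic squamous cell carcinoma
Miscellaneous and site unspecified neoplasms malignant and unspecified	Second primary malignancy
Miscellaneous and site unspecified neoplasms malignant and unspecified	Bladder cancer
Miscellaneous and site unspecified neoplasms malignant and unspecified	Prostate cancer
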