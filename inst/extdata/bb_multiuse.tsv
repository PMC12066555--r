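Entity1	Type1	Attribute1	Entity2	Type2	Attribute2	Direction	R_name	R_label
beta-blockers	MT		heart failure	Diseases		forward	Indications	Indications
beta-blockers	MT		heart failure	Diseases		forward	Indications	Indications
beta-blockers	MT		β-Indications	AMT		forward	AT	AT
β-Indications	AMT		hypertension	Diseases		forward	Indications	Indications
β-Indications	AMT		hereditary long QT	Diseases		forward	Indications	Indications
β-Indications	AMT		congestive heart failure	Diseases		forward	Indications	Indications
beta-blockers	MT		propranolol	Drugs		forward	Contains	Contains
beta-blockers	MT		metoprolol	Drugs		forward	Contains	Contains
beta-blockers	MT		β-Mechanism of action	AMT		forward	AT	AT
β-Mechanism of action	AMT		sympathetic nerve activity regulation	Behaviors		forward	Description	Description
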