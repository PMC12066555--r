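Entity1	Type1	Attribute1	Entity2	Type2	Attribute2	Direction	R_name	R_label
intravenous beta-blockers	Drugs		hypertension	Diseases		reverse	Treatment	Treatment
hypertension and diabetes	Diseases		beta-blockers	MT		forward	Contraindications	Contraindications
hypertension and diabetes	Diseases		hypertension	Diseases		forward	Contains	Contains
hypertension and diabetes	Diseases		diabetes	Diseases		forward	Contains	Contains
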