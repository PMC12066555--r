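Entity1	Type1	Attribute1	Entity2	Type2	Attribute2	Direction	R_name	R_label
propranolol	Drugs		hypertension	Diseases		forward	Indications	Indications
propranolol	Drugs		hypertension	Diseases		forward	Indications	Indications
propranolol	Drugs		myocardial infarction	Diseases		forward	Indications	Indications
hypertension	Diseases		propranolol hypertension dosing	Drug applications	initial_dose=10 mg;max_dose=200 mg;frequency=3–4 times daily;form=tablet	forward	Description	Description
propranolol	Drugs		propranolol hypertension dosing	Drug applications		forward	Description	Description
myocardial infarction	Diseases		propranolol myocardial infarction dosing	Drug applications	dose_range=30–240 mg;frequency=2–3 times daily	forward	Description	Description
propranolol	Drugs		sinus bradycardia	Adverse reactions		forward	Causes	Causes
propranolol	Drugs		atrioventricular block	Adverse reactions		forward	Causes	Causes
propranolol	Drugs		hypotension	Adverse reactions		forward	Causes	Causes
beta-blockers	MT		propranolol	Drugs		forward	Contains	Contains
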