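subject_category	object_category	relations
Diseases	Diseases	Contains
Drugs	AMT	AT;Combination medication
Patients	AMT	Contraindications;Treatment
Drug combinations	Drugs	Drug combination;Combination medication;Contains
Drug effects	AMT	Description;Effects;Causes
Drug effects	Drug characteristics	Description
Drug effects	Drugs	Description;Effects
Drug categories	AMT	Action;Contains
MT	AMT	AT
Symptoms	AMT	Improves;Causes;Indications;Effects
Treatment methods	AMT	Treatment;Indications
Treatment methods	Symptoms	Improves;Treatment
Diseases	Disease stages	Stage
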