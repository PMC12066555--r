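Entity1	Type1	Attribute1	Entity2	Type2	Attribute2	Direction	R_name	R_label
hypertension	Diseases		grade I hypertension	Disease stages		forward	Stage	Stage
grade I hypertension	Disease stages		grade II hypertension	Disease stages		forward	Stage	Stage
grade II hypertension	Disease stages		grade III hypertension	Disease stages		forward	Stage	Stage
grade I hypertension	Disease stages		lifestyle interventions	Treatment methods		forward	Treatment	Treatment
grade I hypertension	Disease stages		ARNI or diuretic monotherapy after 4–12 weeks of monitoring	Treatment methods		forward	Treatment	Treatment
grade II hypertension	Disease stages		ARNI or diuretic monotherapy	Treatment methods		forward	Treatment	Treatment
grade III hypertension	Disease stages		intensive combination antihypertensive therapy	Treatment methods		forward	Treatment	Treatment
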