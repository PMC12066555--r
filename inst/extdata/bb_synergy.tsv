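Entity1	Type1	Attribute1	Entity2	Type2	Attribute2	Direction	R_name	R_label
congestive heart failure	Diseases		metoprolol, bisoprolol, carvedilol and felodipine	Drug combinations		forward	The combined effect is better than	Combination medication
congestive heart failure	Diseases		metoprolol, bisoprolol, carvedilol and felodipine	Drug combinations		forward	The combined effect is better than	Combination medication
congestive heart failure	Diseases		metoprolol, bisoprolol, carvedilol and felodipine	Drug combinations		forward	The combined effect is better than	Combination medication
metoprolol, bisoprolol, carvedilol and felodipine	Drug combinations		metoprolol	Drugs		forward	Drug combination	Drug combination
metoprolol, bisoprolol, carvedilol and felodipine	Drug combinations		bisoprolol	Drugs		forward	Drug combination	Drug combination
metoprolol, bisoprolol, carvedilol and felodipine	Drug combinations		carvedilol	Drugs		forward	Drug combination	Drug combination
metoprolol, bisoprolol, carvedilol and felodipine	Drug combinations		felodipine	Drugs		forward	Drug combination	Drug combination
congestive heart failure	Diseases		beta-blockers with digoxin	Drug combinations		forward	Treatment	Treatment
beta-blockers with digoxin	Drug combinations		digoxin	Drugs		forward	Drug combination	Drug combination
beta-blockers with digoxin	Drug combinations		metoprolol	Drugs		forward	Drug combination	Drug combination
metoprolol, bisoprolol, carvedilol and felodipine	Drug combinations		reduces systemic vascular resistance	Drug effects		forward	Effects	Effects
metoprolol, bisoprolol, carvedilol and felodipine	Drug combinations		increases ejection fraction	Drug effects		forward	Effects	Effects
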